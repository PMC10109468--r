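#' Transcription file schema
#'
#' Describes how a delimited transcription export maps onto the canonical
#' response fields: a column mapping (canonical name -> file header), optional
#' per-field value mappings (raw value -> canonical value), and the text
#' dialect. Because platform export layouts are undocumented and vary, any
#' real export is read through such an adapter; the package ships an identity
#' schema for its own files ([synthetic_schema()]) and a best-guess adapter
#' for DigiVol-style exports ([digivol_schema()]).
#'
#' @param columns Named character vector mapping the canonical fields
#'   `image_id`, `volunteer_id`, `focus`, `occurrence`, `count`, `position`,
#'   `name` (plus optional `timestamp`, `order_index`) to file headers.
#' @param values Named list of named character vectors, one per answer field,
#'   mapping raw file values to canonical vocabulary; unmapped values pass
#'   through unchanged.
#' @param delim,quote,encoding Text dialect (defaults: comma, double quote,
#'   UTF-8).
#' @return An object of class `transcription_schema`.
#' @export
transcription_schema <- function(columns, values = list(), delim = ",",
                                 quote = "\"", encoding = "UTF-8") {
  required <- c("image_id", "volunteer_id", answer_fields())
  missing <- setdiff(required, names(columns))
  if (length(missing)) {
    stop("schema must map column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(columns = columns, values = values, delim = delim, quote = quote,
         encoding = encoding),
    class = "transcription_schema"
  )
}

#' @rdname transcription_schema
#' @export
synthetic_schema <- function() {
  cols <- c(image_id = "image_id", volunteer_id = "volunteer_id",
            order_index = "order_index", focus = "focus",
            occurrence = "occurrence", count = "count",
            position = "position", name = "name")
  transcription_schema(cols)
}

#' @rdname transcription_schema
#' @export
digivol_schema <- function() {
  transcription_schema(
    columns = c(
      image_id = "externalIdentifier",
      volunteer_id = "transcriberID",
      timestamp = "dateTranscribed",
      focus = "isTheImageInFocus",
      occurrence = "areThereAnyMicrofossilsInThisImage",
      count = "howManyMicrofossilsArePresent",
      position = "whereIsTheMicrofossil",
      name = "whatTypeOfMicrofossilIsPresent"
    ),
    values = list(
      focus = c("In focus" = "in_focus", "Out of focus" = "out_of_focus"),
      occurrence = c("With a microfossil" = "fossil",
                     "Without a microfossil" = "no_fossil"),
      position = stats::setNames(
        c("middle", "edge", "middle_and_edge", "none"),
        c("Middle", "Edge", "Middle and edge", "")
      ),
      name = stats::setNames(c("none", "unknown"), c("", "Unknown"))
    )
  )
}

map_values <- function(x, map) {
  if (is.null(map)) return(x)
  hit <- match(x, names(map))
  out <- x
  out[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
  out
}

#' Read a transcription export
#'
#' Reads a delimited transcription file through a [transcription_schema()],
#' producing canonical responses ordered within each image (by the mapped
#' timestamp when present, otherwise file order) with a 1-based
#' `order_index`. Rows that fail validation are quarantined with a reason,
#' never silently dropped; a missing mapped column is an error naming the
#' canonical field.
#'
#' @param path Path to the delimited file.
#' @param schema A [transcription_schema()] (default [synthetic_schema()]).
#' @return A list with `responses` (a valid response table, see
#'   [validate_responses()]) and `quarantined` (tibble: `file_row`, `reason`,
#'   plus the raw mapped fields).
#' @export
read_transcriptions <- function(path, schema = synthetic_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(
    path, delim = schema$delim, quote = schema$quote,
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(encoding = schema$encoding),
    progress = FALSE, show_col_types = FALSE
  )
  cols <- schema$columns
  present <- cols %in% names(raw)
  need <- c("image_id", "volunteer_id", answer_fields())
  missing <- intersect(names(cols)[!present], need)
  if (length(missing)) {
    stop("transcription file missing mapped column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  canon <- tibble::tibble(file_row = seq_len(nrow(raw)))
  for (f in names(cols)) {
    if (cols[[f]] %in% names(raw)) {
      v <- raw[[cols[[f]]]]
      v[is.na(v)] <- ""
      canon[[f]] <- map_values(v, schema$values[[f]])
    }
  }

  reason <- rep(NA_character_, nrow(canon))
  flag <- function(bad, why) {
    sel <- bad & is.na(reason)
    reason[sel] <<- why
  }
  flag(!nzchar(canon$image_id), "image_id: empty")
  flag(!nzchar(canon$volunteer_id), "volunteer_id: empty")
  flag(!canon$focus %in% focus_levels(), "focus: unrecognised value")
  flag(!canon$occurrence %in% occurrence_levels(),
       "occurrence: unrecognised value")
  count_raw <- canon$count
  count_raw[count_raw == sprintf("%d+", 10L)] <- "10" # binned top category
  count_num <- suppressWarnings(as.numeric(count_raw))
  fossil <- canon$occurrence == "fossil"
  bad_count <- fossil & (is.na(count_num) | count_num < 1 |
                           count_num != floor(count_num))
  flag(bad_count, "count: not a positive integer")
  flag(fossil & !canon$position %in% setdiff(position_levels(), "none"),
       "position: unrecognised value")
  flag(fossil & !nzchar(canon$name), "name: empty")

  quarantined <- canon[!is.na(reason), , drop = FALSE]
  quarantined$reason <- reason[!is.na(reason)]
  ok <- canon[is.na(reason), , drop = FALSE]
  if (nrow(quarantined)) {
    message(sprintf("read_transcriptions: quarantined %d of %d row(s)",
                    nrow(quarantined), nrow(canon)))
  }

  # a no-fossil answer carries no count/position/name
  nf <- ok$occurrence == "no_fossil"
  count_ok <- count_num[is.na(reason)]
  count_ok[nf] <- 0
  ok$position[nf] <- "none"
  ok$name[nf] <- "none"

  # order within image: timestamp when available, else file order
  if ("timestamp" %in% names(ok) && all(nzchar(ok$timestamp))) {
    ord <- order(ok$image_id, ok$timestamp, ok$file_row)
  } else {
    ord <- order(ok$image_id, ok$file_row)
  }
  ok <- ok[ord, , drop = FALSE]
  count_ok <- count_ok[ord]
  responses <- tibble::tibble(
    image_id = ok$image_id,
    volunteer_id = ok$volunteer_id,
    order_index = as.integer(stats::ave(seq_len(nrow(ok)), ok$image_id,
                                        FUN = seq_along)),
    focus = ok$focus,
    occurrence = ok$occurrence,
    count = as.integer(count_ok),
    position = ok$position,
    name = ok$name
  )
  list(responses = validate_responses(responses), quarantined = quarantined)
}

#' Write responses as a delimited transcription file
#'
#' Inverse of [read_transcriptions()]: canonical values are mapped back
#' through the schema's value maps and written under the schema's headers, in
#' response order.
#'
#' @param responses A valid response table.
#' @param path Output path.
#' @param schema A [transcription_schema()].
#' @return `path`, invisibly.
#' @export
write_transcriptions <- function(responses, path,
                                 schema = synthetic_schema()) {
  responses <- validate_responses(responses)
  out <- tibble::tibble(.rows = nrow(responses))
  for (f in names(schema$columns)) {
    if (is.null(responses[[f]])) next
    v <- as.character(responses[[f]])
    map <- schema$values[[f]]
    if (!is.null(map)) { # invert the value map
      inv <- stats::setNames(names(map), unname(map))
      v <- map_values(v, inv)
    }
    out[[schema$columns[[f]]]] <- v
  }
  readr::write_delim(out, path, delim = schema$delim, quote = "needed")
  invisible(path)
}

#' Write and read detection tables
#'
#' One row per detection, delimited text; see [expert_verify()].
#'
#' @param detections A detection table.
#' @param path File path.
#' @return `path` (writer, invisibly) or a tibble (reader).
#' @export
write_detections <- function(detections, path) {
  readr::write_csv(detections, path)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    col = readr::col_integer(), row = readr::col_integer(),
    x_local_um = readr::col_double(), y_local_um = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
}

#' Write a census table as delimited text and JSON
#'
#' The delimited layout mirrors a published per-taxon summary: taxon, count,
#' percent of identifiable specimens, density per cm^2.
#'
#' @param census A [census_table()].
#' @param path Output path; `write_census_json()` appends the totals.
#' @param seed Optional master seed recorded in the JSON header.
#' @return `path`, invisibly.
#' @export
write_census_csv <- function(census, path) {
  readr::write_csv(
    census$taxa[, c("taxon", "count", "percent", "density_per_cm2")], path
  )
  invisible(path)
}

#' @rdname write_census_csv
#' @export
write_census_json <- function(census, path, seed = NULL) {
  payload <- list(
    report = "census",
    seed = seed,
    totals = census$totals,
    taxa = census$taxa
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a flow report as JSON
#'
#' @param flow A [flow_report()].
#' @param path Output path.
#' @param seed Optional master seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_flow_json <- function(flow, path, seed = NULL) {
  payload <- c(list(report = "flow", seed = seed), unclass(flow))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Validate a written report against the shipped report schema
#'
#' The package publishes a minimal JSON schema
#' (`inst/extdata/report-schema.json`) naming the required fields and types
#' of each report it writes; this checks a parsed report against it.
#'
#' @param report A parsed report (list) or a path to a JSON report.
#' @param type One of `"flow"`, `"census"`, `"performance"`.
#' @return `TRUE` invisibly, or an error naming the first violation.
#' @export
validate_report <- function(report, type = c("flow", "census",
                                             "performance")) {
  type <- match.arg(type)
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema_path <- system.file("extdata", "report-schema.json",
                             package = "palycensus")
  schema <- jsonlite::read_json(schema_path)
  spec <- schema[[type]]
  if (is.null(spec)) stop("no schema for report type ", type, call. = FALSE)
  for (field in names(spec$required)) {
    if (is.null(report[[field]])) {
      stop(sprintf("report missing required field `%s`", field),
           call. = FALSE)
    }
    want <- spec$required[[field]]
    got <- report[[field]]
    ok <- switch(want,
      integer = is.numeric(got) || (is.list(got) && all(vapply(got, is.numeric, logical(1)))),
      number = is.numeric(got),
      string = is.character(got),
      object = is.list(got),
      array = is.list(got) || is.vector(got),
      TRUE
    )
    if (!ok) {
      stop(sprintf("report field `%s` is not of type %s", field, want),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
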
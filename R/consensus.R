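# Canonical questionnaire vocabulary. Every transcription answers all five
# questions; a "no fossil" answer forces count 0, position "none", name "none".

answer_fields <- function() c("focus", "occurrence", "count", "position", "name")

focus_levels <- function() c("in_focus", "out_of_focus")
occurrence_levels <- function() c("fossil", "no_fossil")
position_levels <- function() c("middle", "edge", "middle_and_edge", "none")

verdict_categories <- function() {
  c("AGREEMENT_FOSSIL", "AGREEMENT_NO_FOSSIL", "NO_AGREEMENT", "PENDING")
}

key_sep <- "\x1f"

response_cols <- function() {
  c("image_id", "volunteer_id", "order_index", answer_fields())
}

# field-separated matching key over the requested answer fields
response_key <- function(responses, fields = answer_fields()) {
  do.call(paste, c(lapply(fields, function(f) responses[[f]]), sep = key_sep))
}

#' Validate a table of transcription responses
#'
#' Checks column presence, questionnaire vocabulary, and the structural
#' invariant that a `no_fossil` response carries `count = 0`,
#' `position = "none"`, `name = "none"`, and that `order_index` is unique
#' within each image.
#'
#' @param responses A data frame with columns `image_id`, `volunteer_id`,
#'   `order_index`, `focus`, `occurrence`, `count`, `position`, `name`.
#' @return The validated responses as a [tibble::tibble()] (invisibly
#'   coerced), or an error describing the first violation.
#' @export
validate_responses <- function(responses) {
  missing <- setdiff(response_cols(), names(responses))
  if (length(missing)) {
    stop("responses missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  responses <- tibble::as_tibble(responses)
  if (!all(responses$focus %in% focus_levels())) {
    stop("invalid `focus` value", call. = FALSE)
  }
  if (!all(responses$occurrence %in% occurrence_levels())) {
    stop("invalid `occurrence` value", call. = FALSE)
  }
  if (!all(responses$position %in% position_levels())) {
    stop("invalid `position` value", call. = FALSE)
  }
  if (!is.numeric(responses$count) || any(is.na(responses$count)) ||
      any(responses$count < 0) || any(responses$count != floor(responses$count))) {
    stop("`count` must be non-negative integers", call. = FALSE)
  }
  nf <- responses$occurrence == "no_fossil"
  if (any(responses$count[nf] != 0) || any(responses$position[nf] != "none") ||
      any(responses$name[nf] != "none")) {
    stop("`no_fossil` responses must have count 0, position 'none', name 'none'",
         call. = FALSE)
  }
  dup <- duplicated(responses[c("image_id", "order_index")])
  if (any(dup)) {
    stop("duplicate order_index within image(s): ",
         paste(utils::head(unique(responses$image_id[dup]), 5), collapse = ", "),
         call. = FALSE)
  }
  responses
}

collapse_sublabel <- function(name, occurrence) {
  ifelse(occurrence != "fossil", "none",
         ifelse(name == "unknown", "unknown", "pollen_or_spore"))
}

#' Aggregate the responses for one image into a verdict
#'
#' Implements the serving-order consensus decision tree. Scanning responses
#' in arrival order, the image closes at the first moment `quorum` responses
#' are pairwise identical on all matched answer fields. The verdict category
#' follows the agreeing responses' occurrence answer. An image validated as
#' containing no fossil is flagged *disputed* when at least one dissenting
#' fossil report arrived before closure. If `max_views` responses arrive with
#' no quorum-identical subset the verdict is `NO_AGREEMENT`; an unclosed
#' stream shorter than `max_views` is `PENDING` (the stream was truncated
#' before serving could finish).
#'
#' @param responses Responses for a single image (see [validate_responses()]),
#'   sorted by `order_index` (re-sorted defensively).
#' @param quorum Number of identical responses required to validate (default 3).
#' @param max_views Maximum number of views served per image (default 4).
#' @param match_fields Answer fields that must agree exactly for validation;
#'   default all five questionnaire fields.
#' @param order_aware If `TRUE` (default) a dispute requires the fossil report
#'   to precede closure; if `FALSE` any fossil report among the responses of a
#'   no-fossil-validated image disputes it.
#' @return A one-row [tibble::tibble()]: `image_id`, `category`, `disputed`,
#'   `fossil_sublabel`, `disagreement_fields` (comma-separated, `""` when all
#'   responses agree), `n_responses` (views consumed up to closure).
#' @examples
#' r <- tibble::tibble(
#'   image_id = "img", volunteer_id = paste0("v", 1:4), order_index = 1:4,
#'   focus = "in_focus",
#'   occurrence = c("no_fossil", "fossil", "no_fossil", "no_fossil"),
#'   count = c(0L, 1L, 0L, 0L),
#'   position = c("none", "middle", "none", "none"),
#'   name = c("none", "unknown", "none", "none"))
#' aggregate_image(r)  # AGREEMENT_NO_FOSSIL, disputed
#' @export
aggregate_image <- function(responses, quorum = 3, max_views = 4,
                            match_fields = answer_fields(),
                            order_aware = TRUE) {
  if (quorum > max_views) stop("`quorum` must be <= `max_views`", call. = FALSE)
  responses <- validate_responses(responses)
  if (length(unique(responses$image_id)) > 1L) {
    stop("`aggregate_image()` expects responses for a single image",
         call. = FALSE)
  }
  n <- nrow(responses)
  if (n > max_views) {
    stop(sprintf("more than max_views = %d responses for image %s",
                 max_views, responses$image_id[1]), call. = FALSE)
  }
  responses <- responses[order(responses$order_index), , drop = FALSE]
  keys <- response_key(responses, match_fields)

  closed_at <- NA_integer_
  agree_key <- NA_character_
  if (n >= quorum) {
    for (t in quorum:n) {
      tab <- table(keys[seq_len(t)])
      hit <- names(tab)[tab >= quorum]
      if (length(hit)) {
        closed_at <- t
        agree_key <- hit[[1L]]
        break
      }
    }
  }

  img <- responses$image_id[1]
  if (!is.na(closed_at)) {
    used <- responses[seq_len(closed_at), , drop = FALSE]
    agree_rows <- used[keys[seq_len(closed_at)] == agree_key, , drop = FALSE]
    occ <- agree_rows$occurrence[1]
    category <- if (occ == "fossil") "AGREEMENT_FOSSIL" else "AGREEMENT_NO_FOSSIL"
    dispute_scope <- if (order_aware) used else responses
    disputed <- category == "AGREEMENT_NO_FOSSIL" &&
      any(dispute_scope$occurrence == "fossil")
    sublabel <- collapse_sublabel(agree_rows$name[1], occ)
    dis <- fields_in_disagreement(used)
    n_resp <- closed_at
  } else {
    category <- if (n >= max_views) "NO_AGREEMENT" else "PENDING"
    disputed <- FALSE
    sublabel <- "none"
    dis <- if (n >= 2) fields_in_disagreement(responses) else character(0)
    n_resp <- n
  }
  tibble::tibble(
    image_id = img,
    category = category,
    disputed = disputed,
    fossil_sublabel = sublabel,
    disagreement_fields = paste(dis, collapse = ","),
    n_responses = as.integer(n_resp)
  )
}

# internal: fields (canonical order) on which not all responses agree
fields_in_disagreement <- function(responses, fields = answer_fields()) {
  fields[vapply(fields, function(f) {
    length(unique(responses[[f]])) > 1L
  }, logical(1))]
}

#' Answer fields on which volunteers disagreed
#'
#' @param responses Responses for one image; at least two rows.
#' @param fields Fields to compare (default all five questionnaire fields).
#' @return Character vector (possibly empty) of disagreeing fields in
#'   canonical order (`focus`, `occurrence`, `count`, `position`, `name`).
#' @export
disagreement_fields <- function(responses, fields = answer_fields()) {
  if (nrow(responses) < 2L) {
    stop("`disagreement_fields()` needs at least 2 responses", call. = FALSE)
  }
  fields_in_disagreement(responses, fields)
}

#' Aggregate many images at once
#'
#' Vectorised equivalent of applying [aggregate_image()] per image; suitable
#' for full-expedition tables (tens of thousands of images).
#'
#' @inheritParams aggregate_image
#' @param responses A response table covering any number of images.
#' @return A [tibble::tibble()] of verdicts, one row per image, sorted by
#'   `image_id` (columns as in [aggregate_image()]).
#' @export
consensus_verdicts <- function(responses, quorum = 3, max_views = 4,
                               match_fields = answer_fields(),
                               order_aware = TRUE) {
  if (quorum > max_views) stop("`quorum` must be <= `max_views`", call. = FALSE)
  responses <- validate_responses(responses)
  if (nrow(responses) == 0L) {
    return(aggregate_image(responses[0, ], quorum, max_views)[0, ])
  }
  responses <- responses[order(responses$image_id, responses$order_index), ,
                         drop = FALSE]
  ids <- unique(responses$image_id)
  ridx <- match(responses$image_id, ids)
  n_img <- length(ids)
  n_resp <- tabulate(ridx, nbins = n_img)
  if (any(n_resp > max_views)) {
    stop(sprintf("more than max_views = %d responses for image %s", max_views,
                 ids[which(n_resp > max_views)[1]]), call. = FALSE)
  }

  key <- response_key(responses, match_fields)
  mv <- max_views
  kmat <- matrix(NA_character_, n_img, mv)
  pos <- stats::ave(seq_along(ridx), ridx, FUN = seq_along)
  kmat[cbind(ridx, pos)] <- key
  occ <- matrix(NA_character_, n_img, mv)
  occ[cbind(ridx, pos)] <- responses$occurrence
  nam <- matrix(NA_character_, n_img, mv)
  nam[cbind(ridx, pos)] <- responses$name

  closed_at <- rep(NA_integer_, n_img)
  pivot <- rep(NA_integer_, n_img)
  if (mv >= quorum) {
    for (t in quorum:mv) {
      open <- which(is.na(closed_at) & n_resp >= t)
      if (!length(open)) next
      sub <- kmat[open, seq_len(t), drop = FALSE]
      # count, for each candidate pivot column j, matches among first t views
      for (j in seq_len(t)) {
        cnt <- rowSums(sub == sub[, j])
        hit <- cnt >= quorum & is.na(closed_at[open])
        if (any(hit)) {
          closed_at[open[hit]] <- t
          pivot[open[hit]] <- j
        }
      }
    }
  }

  closed <- !is.na(closed_at)
  category <- rep("PENDING", n_img)
  category[!closed & n_resp >= max_views] <- "NO_AGREEMENT"
  agree_occ <- rep(NA_character_, n_img)
  agree_name <- rep(NA_character_, n_img)
  agree_occ[closed] <- occ[cbind(which(closed), pivot[closed])]
  agree_name[closed] <- nam[cbind(which(closed), pivot[closed])]
  category[closed] <- ifelse(agree_occ[closed] == "fossil",
                             "AGREEMENT_FOSSIL", "AGREEMENT_NO_FOSSIL")

  used <- ifelse(closed, closed_at, n_resp)
  # dispute: any fossil report among the responses in scope
  fossil_flag <- !is.na(occ) & occ == "fossil"
  in_scope <- if (order_aware) {
    col(fossil_flag) <= matrix(used, n_img, mv)
  } else {
    col(fossil_flag) <= matrix(n_resp, n_img, mv)
  }
  any_fossil <- rowSums(fossil_flag & in_scope) > 0
  disputed <- category == "AGREEMENT_NO_FOSSIL" & any_fossil

  sublabel <- rep("none", n_img)
  af <- category == "AGREEMENT_FOSSIL"
  sublabel[af] <- ifelse(agree_name[af] == "unknown", "unknown",
                         "pollen_or_spore")

  # disagreement fields over the consumed responses
  dis <- matrix(FALSE, n_img, length(answer_fields()))
  colnames(dis) <- answer_fields()
  used_mask <- col(kmat) <= matrix(used, n_img, mv)
  for (f in answer_fields()) {
    m <- matrix(NA_character_, n_img, mv)
    m[cbind(ridx, pos)] <- as.character(responses[[f]])
    m[!used_mask] <- NA_character_
    first <- m[cbind(seq_len(n_img), pmin(used, 1L))]
    first[used == 0L] <- NA_character_
    differs <- m != matrix(first, n_img, mv)
    dis[, f] <- rowSums(differs, na.rm = TRUE) > 0
  }
  dis_str <- apply(dis, 1L, function(z) paste(answer_fields()[z], collapse = ","))

  tibble::tibble(
    image_id = ids,
    category = category,
    disputed = disputed,
    fossil_sublabel = sublabel,
    disagreement_fields = dis_str,
    n_responses = as.integer(used)
  )
}

#' Flow accounting over a set of verdicts
#'
#' Tallies the consensus outcomes the way an expedition flow chart reports
#' them: total images, agreements split into no-fossil (undisputed/disputed)
#' and fossil (pollen-or-spore / unknown), no-agreements, and the resulting
#' expert-review queue (fossil agreements + disputed + no-agreement).
#'
#' @param verdicts A verdict table from [consensus_verdicts()] or
#'   [aggregate_image()].
#' @return An object of class `flow_report`: a list of counts `n_images`,
#'   `n_agreement`, `n_agreement_no_fossil`, `n_agreement_fossil`,
#'   `n_fossil_pollen_spore`, `n_fossil_unknown`, `n_disputed`,
#'   `n_no_agreement`, `n_review_queue`, plus `n_pending` (tallied separately;
#'   `n_images` counts closed images only).
#' @export
flow_report <- function(verdicts) {
  cat_ <- verdicts$category
  n_pending <- sum(cat_ == "PENDING")
  closed <- cat_ != "PENDING"
  n_anf <- sum(cat_ == "AGREEMENT_NO_FOSSIL")
  n_af <- sum(cat_ == "AGREEMENT_FOSSIL")
  n_na <- sum(cat_ == "NO_AGREEMENT")
  n_disputed <- sum(verdicts$disputed)
  out <- list(
    n_images = sum(closed),
    n_agreement = n_anf + n_af,
    n_agreement_no_fossil = n_anf,
    n_agreement_fossil = n_af,
    n_fossil_pollen_spore = sum(verdicts$fossil_sublabel == "pollen_or_spore"),
    n_fossil_unknown = sum(verdicts$fossil_sublabel == "unknown"),
    n_disputed = n_disputed,
    n_no_agreement = n_na,
    n_review_queue = n_af + n_disputed + n_na,
    n_pending = n_pending
  )
  structure(lapply(out, as.integer), class = "flow_report")
}

#' @export
print.flow_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<flow_report> %d closed images (%d pending)\n",
      "  agreement: %d\n",
      "    no fossil: %d (disputed: %d)\n",
      "    fossil:    %d (pollen/spore: %d, unknown: %d)\n",
      "  no agreement: %d\n",
      "  expert-review queue: %d\n"
    ),
    x$n_images, x$n_pending, x$n_agreement, x$n_agreement_no_fossil,
    x$n_disputed, x$n_agreement_fossil, x$n_fossil_pollen_spore,
    x$n_fossil_unknown, x$n_no_agreement, x$n_review_queue
  ))
  invisible(x)
}

#' Decompose no-agreement images by disagreement reason
#'
#' @param verdicts A verdict table.
#' @return A [tibble::tibble()] with `disagreement_fields` (comma-separated
#'   combination) and `n`, sorted by decreasing `n`, over `NO_AGREEMENT`
#'   images only.
#' @export
disagreement_breakdown <- function(verdicts) {
  na_ <- verdicts[verdicts$category == "NO_AGREEMENT", , drop = FALSE]
  if (nrow(na_) == 0L) {
    return(tibble::tibble(disagreement_fields = character(0), n = integer(0)))
  }
  tab <- sort(table(na_$disagreement_fields), decreasing = TRUE)
  tibble::tibble(
    disagreement_fields = names(tab),
    n = as.integer(tab)
  )
}
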
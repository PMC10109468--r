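#' Collapse overlap duplicates into unique specimens
#'
#' Detections are mapped to montage-global coordinates and merged by
#' single-linkage clustering: any two detections within `epsilon_um` of each
#' other (transitively) belong to one unique specimen. This undoes the
#' duplication created by the tile overlap, where a specimen sitting in an
#' overlap strip is imaged (and detected) in two or four neighbouring tiles.
#' Detections from different montages are never merged. The cluster's label
#' is the majority detection label, ties resolved to `"indeterminable"`.
#'
#' @param detections A detection table (`image_id`, `montage`, `col`, `row`,
#'   `x_local_um`, `y_local_um`, `label`, ...), e.g. from [expert_verify()].
#' @param grids The montage grids (a [tile_grid()] or named list).
#' @param epsilon_um Merge tolerance in micrometres (>= 0; default 10, the
#'   order of a pollen-grain radius).
#' @return A list with `specimens` (one row per unique specimen: `specimen_uid`,
#'   `montage`, `x_um`, `y_um` centroid, `taxon`, `n_detections`) and
#'   `detections` (the input plus `specimen_uid`).
#' @export
deduplicate_detections <- function(detections, grids, epsilon_um = 10) {
  if (!is.numeric(epsilon_um) || epsilon_um < 0) {
    stop("`epsilon_um` must be >= 0", call. = FALSE)
  }
  grids <- as_grid_list(grids)
  detections <- tibble::as_tibble(detections)
  n <- nrow(detections)
  if (n == 0L) {
    return(list(
      specimens = tibble::tibble(
        specimen_uid = character(0), montage = character(0),
        x_um = numeric(0), y_um = numeric(0), taxon = character(0),
        n_detections = integer(0)
      ),
      detections = dplyr::mutate(detections, specimen_uid = character(0))
    ))
  }
  unknown <- setdiff(unique(detections$montage), names(grids))
  if (length(unknown)) {
    stop("detections refer to unknown montage(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  gx <- numeric(n)
  gy <- numeric(n)
  for (mid in unique(detections$montage)) {
    sel <- detections$montage == mid
    glob <- local_to_global(grids[[mid]], detections$col[sel],
                            detections$row[sel], detections$x_local_um[sel],
                            detections$y_local_um[sel])
    gx[sel] <- glob$x_um
    gy[sel] <- glob$y_um
  }

  cluster <- integer(n)
  offset <- 0L
  for (mid in unique(detections$montage)) {
    sel <- which(detections$montage == mid)
    if (length(sel) == 1L) {
      cluster[sel] <- offset + 1L
      offset <- offset + 1L
    } else {
      hc <- stats::hclust(stats::dist(cbind(gx[sel], gy[sel])),
                          method = "single")
      cl <- stats::cutree(hc, h = epsilon_um)
      cluster[sel] <- offset + cl
      offset <- offset + max(cl)
    }
  }

  label <- detections$label
  specs <- lapply(split(seq_len(n), cluster), function(ix) {
    tab <- sort(table(label[ix]), decreasing = TRUE)
    taxon <- if (length(tab) > 1L && tab[1] == tab[2]) {
      "indeterminable"
    } else {
      names(tab)[1]
    }
    tibble::tibble(
      montage = detections$montage[ix[1]],
      x_um = mean(gx[ix]), y_um = mean(gy[ix]),
      taxon = taxon, n_detections = length(ix)
    )
  })
  specimens <- dplyr::bind_rows(specs)
  specimens <- dplyr::bind_cols(
    tibble::tibble(specimen_uid = sprintf("u%05d", seq_len(nrow(specimens)))),
    specimens
  )
  detections$specimen_uid <- specimens$specimen_uid[cluster]
  list(specimens = specimens, detections = detections)
}

#' Palynomorph census: counts, relative abundance, density
#'
#' Per-taxon unique-specimen counts, the percentage of identifiable
#' specimens, and the areal density in specimens per square centimetre.
#' Percentages use the identifiable specimens as the base (indeterminable
#' specimens are counted but not attributed); a percentage of all specimens
#' is reported alongside. Reported densities are rounded to one decimal and
#' percentages to integers; exact values are kept in the table.
#'
#' @param unique_specimens A table with one row per unique specimen and a
#'   `taxon` column (e.g. `specimens` from [deduplicate_detections()], or a
#'   ground-truth field from [generate_specimens()]).
#' @param total_area_cm2 Imaged area in cm^2 (> 0).
#' @return An object of class `census_table`: list with `taxa` (tibble:
#'   `taxon`, `count`, `percent`, `percent_exact`, `percent_of_total`,
#'   `density_per_cm2`, `density_exact`) and `totals` (`n_unique`,
#'   `n_identifiable`, `n_indeterminable`, `total_area_cm2`,
#'   `density_per_cm2`).
#' @examples
#' field <- tibble::tibble(taxon = rep(c("Nothofagidites", "fungal_spore"),
#'                                     c(134, 60)))
#' census_table(field, 1.85)
#' @export
census_table <- function(unique_specimens, total_area_cm2) {
  if (!is.numeric(total_area_cm2) || length(total_area_cm2) != 1L ||
      !is.finite(total_area_cm2) || total_area_cm2 <= 0) {
    stop("`total_area_cm2` must be a single positive number", call. = FALSE)
  }
  taxon <- unique_specimens$taxon
  n_unique <- length(taxon)
  indet <- taxon == "indeterminable"
  n_ident <- sum(!indet)
  tab <- table(taxon[!indet])
  tab <- sort(tab, decreasing = TRUE)
  counts <- as.integer(tab)
  taxa <- tibble::tibble(
    taxon = if (length(tab)) names(tab) else character(0),
    count = counts,
    percent = as.integer(round(100 * counts / max(1L, n_ident))),
    percent_exact = 100 * counts / max(1L, n_ident),
    percent_of_total = 100 * counts / max(1L, n_unique),
    density_per_cm2 = round(counts / total_area_cm2, 1),
    density_exact = counts / total_area_cm2
  )
  structure(
    list(
      taxa = taxa,
      totals = list(
        n_unique = n_unique,
        n_identifiable = n_ident,
        n_indeterminable = sum(indet),
        total_area_cm2 = total_area_cm2,
        density_per_cm2 = n_unique / total_area_cm2
      )
    ),
    class = "census_table"
  )
}

#' @export
print.census_table <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "<census_table> %d unique specimens (%d identifiable, %d indeterminable) over %.4g cm^2\n",
    t$n_unique, t$n_identifiable, t$n_indeterminable, t$total_area_cm2
  ))
  print(as.data.frame(x$taxa[, c("taxon", "count", "percent",
                                 "density_per_cm2")]), row.names = FALSE)
  invisible(x)
}

#' Extrapolate specimens overlooked by the whole pipeline
#'
#' A full manual audit of a subset of images yields a count of specimens the
#' pipeline missed; scaling linearly to the whole dataset estimates the total
#' overlooked, with a binomial standard error.
#'
#' @param missed_in_audit Specimens found only by the audit (>= 0).
#' @param audit_n_images Number of audited images (> 0).
#' @param total_n_images Total images in the dataset.
#' @return A list with `estimate` and `se`.
#' @examples
#' estimate_overlooked(7, 1000, 25200)  # 176.4
#' @export
estimate_overlooked <- function(missed_in_audit, audit_n_images,
                                total_n_images) {
  if (audit_n_images <= 0) stop("`audit_n_images` must be > 0", call. = FALSE)
  if (missed_in_audit < 0 || missed_in_audit > audit_n_images) {
    stop("`missed_in_audit` must be in [0, audit_n_images]", call. = FALSE)
  }
  p <- missed_in_audit / audit_n_images
  list(
    estimate = missed_in_audit * total_n_images / audit_n_images,
    se = total_n_images * sqrt(p * (1 - p) / audit_n_images)
  )
}

#' Audit the pipeline against the ground-truth specimen field
#'
#' Matches ground-truth specimens to deduplicated census specimens within
#' `epsilon_um` (greedy nearest-pair, one-to-one, within montage) and reports
#' recall, the missed specimens, and spurious census entries.
#'
#' @param specimens Ground truth from [generate_specimens()].
#' @param census_specimens The `specimens` table from
#'   [deduplicate_detections()].
#' @param epsilon_um Match tolerance in micrometres (default 10).
#' @return A list: `recall`, `n_truth`, `n_matched`, `missed` (tibble of
#'   unmatched ground-truth specimens), `n_false` (census specimens matching
#'   no ground truth).
#' @export
detection_performance <- function(specimens, census_specimens,
                                  epsilon_um = 10) {
  n_truth <- nrow(specimens)
  matched_truth <- logical(n_truth)
  matched_cens <- logical(nrow(census_specimens))
  for (mid in unique(specimens$montage)) {
    ti <- which(specimens$montage == mid)
    ci <- which(census_specimens$montage == mid)
    if (!length(ti) || !length(ci)) next
    d <- sqrt(outer(specimens$x_um[ti], census_specimens$x_um[ci], "-")^2 +
                outer(specimens$y_um[ti], census_specimens$y_um[ci], "-")^2)
    repeat {
      m <- which.min(d)
      if (!length(m) || d[m] > epsilon_um || !is.finite(d[m])) break
      i <- (m - 1L) %% length(ti) + 1L
      j <- (m - 1L) %/% length(ti) + 1L
      matched_truth[ti[i]] <- TRUE
      matched_cens[ci[j]] <- TRUE
      d[i, ] <- Inf
      d[, j] <- Inf
    }
  }
  list(
    recall = if (n_truth > 0) sum(matched_truth) / n_truth else NA_real_,
    n_truth = n_truth,
    n_matched = sum(matched_truth),
    missed = specimens[!matched_truth, , drop = FALSE],
    n_false = sum(!matched_cens)
  )
}
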
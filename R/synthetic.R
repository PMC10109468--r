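#' Taxon mixture for the synthetic specimen field
#'
#' A named vector of relative frequencies over taxon labels plus an
#' `indeterminable` fraction; frequencies must be non-negative and sum to 1.
#'
#' @param frequencies Named numeric vector; must include an `indeterminable`
#'   entry (use 0 for none).
#' @return An object of class `taxon_mix`.
#' @export
taxon_mix <- function(frequencies) {
  if (is.null(names(frequencies)) || any(!nzchar(names(frequencies)))) {
    stop("`frequencies` must be a named numeric vector", call. = FALSE)
  }
  if (!"indeterminable" %in% names(frequencies)) {
    stop("`frequencies` must include an `indeterminable` entry", call. = FALSE)
  }
  if (any(frequencies < 0) || abs(sum(frequencies) - 1) > 1e-8) {
    stop("frequencies must be >= 0 and sum to 1", call. = FALSE)
  }
  structure(frequencies, class = "taxon_mix")
}

#' Default palynomorph mixture
#'
#' Mirrors the relative abundances observed in the survey this package
#' emulates: among identifiable specimens, southern-beech pollen
#' (*Nothofagidites*) 44%, fungal spores 20%, fern/moss spores 9%, and the
#' remaining 27% spread over rarer categories; 83/383 of all specimens are
#' indeterminable.
#'
#' @return A [taxon_mix()].
#' @export
default_taxon_mix <- function() {
  identifiable <- c(
    Nothofagidites = 0.44,
    fungal_spore = 0.20,
    fern_moss_spore = 0.09,
    saccate_pollen = 0.06,
    myrtaceae_pollen = 0.06,
    triporate_pollen = 0.05,
    araucariaceae_pollen = 0.04,
    other_angiosperm_pollen = 0.06
  )
  p_ident <- 300 / 383
  taxon_mix(c(identifiable * p_ident, indeterminable = 83 / 383))
}

mix_taxa <- function(mix) setdiff(names(mix), "indeterminable")

#' Volunteer profiles for the transcription simulator
#'
#' Each volunteer has a per-specimen detection probability (`sensitivity`), a
#' probability of reporting a fossil in an empty image
#' (`false_positive_rate`), a probability of mis-stating the count by one
#' (`count_error_rate`), a probability of answering the focus question wrong
#' (`focus_error_rate`), a probability of skipping a served image
#' (`skip_rate`), and a relative propensity to transcribe
#' (`activity_weight`). A shared row-stochastic naming-confusion matrix over
#' taxon labels plus `"unknown"` is attached as attribute `name_confusion`.
#'
#' Activity weights are drawn from a Pareto distribution whose shape is
#' chosen so that the most active tenth of volunteers performs roughly 85% of
#' all transcriptions, matching the strong engagement skew typical of online
#' expeditions. The remaining error rates default to values calibrated so
#' that, with quorum 3 and up to 4 views, the expected flow through the
#' decision tree (disputed, no-agreement and review-queue proportions)
#' matches the survey this package emulates.
#'
#' @param n Number of volunteers (default 271).
#' @param sensitivity,false_positive_rate,count_error_rate,focus_error_rate,skip_rate
#'   Probabilities in `[0, 1]`, recycled across volunteers.
#' @param activity_shape Pareto shape for activity weights (default 1.076,
#'   giving a ~85% share to the top decile in expectation).
#' @param name_accuracy Probability a detected specimen's taxon is named
#'   correctly (default 0.65); `unknown_rate` (default 0.20) is the
#'   probability of answering `"unknown"`, the remainder is spread uniformly
#'   over the other taxa.
#' @param taxa Character vector of identifiable taxon labels (default: taxa of
#'   [default_taxon_mix()]).
#' @param seed Optional integer seed for the activity-weight draw.
#' @return A [tibble::tibble()] of class `volunteer_profiles` with attribute
#'   `name_confusion`.
#' @export
volunteer_profiles <- function(n = 271, sensitivity = 0.9,
                               false_positive_rate = 0.042,
                               count_error_rate = 0.30,
                               focus_error_rate = 0.07,
                               skip_rate = 0,
                               activity_shape = 1.076,
                               name_accuracy = 0.65, unknown_rate = 0.20,
                               taxa = mix_taxa(default_taxon_mix()),
                               seed = NULL) {
  probs <- list(sensitivity = sensitivity,
                false_positive_rate = false_positive_rate,
                count_error_rate = count_error_rate,
                focus_error_rate = focus_error_rate,
                skip_rate = skip_rate)
  for (nm in names(probs)) {
    if (any(probs[[nm]] < 0 | probs[[nm]] > 1)) {
      stop(sprintf("`%s` must be in [0, 1]", nm), call. = FALSE)
    }
  }
  if (name_accuracy + unknown_rate > 1) {
    stop("`name_accuracy` + `unknown_rate` must be <= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  # Pareto(shape, x_min = 1) by inversion
  w <- (1 - stats::runif(n))^(-1 / activity_shape)
  prof <- tibble::tibble(
    volunteer_id = sprintf("vol_%04d", seq_len(n)),
    sensitivity = rep_len(sensitivity, n),
    false_positive_rate = rep_len(false_positive_rate, n),
    count_error_rate = rep_len(count_error_rate, n),
    focus_error_rate = rep_len(focus_error_rate, n),
    skip_rate = rep_len(skip_rate, n),
    activity_weight = w
  )
  attr(prof, "name_confusion") <-
    name_confusion_matrix(taxa, name_accuracy, unknown_rate)
  class(prof) <- c("volunteer_profiles", class(prof))
  prof
}

# row-stochastic confusion over true labels (taxa + indeterminable) ->
# answered labels (taxa + unknown)
name_confusion_matrix <- function(taxa, name_accuracy = 0.65,
                                  unknown_rate = 0.20) {
  k <- length(taxa)
  labels_out <- c(taxa, "unknown")
  m <- matrix(0, nrow = k + 1L, ncol = k + 1L,
              dimnames = list(c(taxa, "indeterminable"), labels_out))
  spread <- (1 - name_accuracy - unknown_rate) / max(1L, k - 1L)
  for (i in seq_len(k)) {
    m[i, ] <- spread
    m[i, taxa[i]] <- name_accuracy
    m[i, "unknown"] <- unknown_rate
  }
  m["indeterminable", ] <- c(rep(0.15 / k, k), 0.85)
  stopifnot(all(abs(rowSums(m) - 1) < 1e-12))
  m
}

#' Generate a synthetic planar specimen field
#'
#' Specimens are placed by a homogeneous Poisson point process over each
#' montage's (unrounded) extent: the per-montage count is Poisson with mean
#' `density_per_cm2 * area_cm2_exact` and positions are uniform. Taxa are
#' sampled from `mix`; radii from `radius_model`.
#'
#' @param grids A named list of [tile_grid()] (or a single grid); names become
#'   montage ids (`m1`, `m2`, ... when unnamed).
#' @param density_per_cm2 Expected unique specimens per cm^2 (>= 0).
#' @param mix A [taxon_mix()].
#' @param radius_model Function `n -> radii (um)`; default log-normal with
#'   median 12 um (typical pollen-grain scale).
#' @param seed Optional integer seed.
#' @return A [tibble::tibble()]: `specimen_id`, `montage`, `x_um`, `y_um`
#'   (montage-global), `radius_um`, `taxon`, `identifiable`.
#' @export
generate_specimens <- function(grids, density_per_cm2,
                               mix = default_taxon_mix(),
                               radius_model = NULL, seed = NULL) {
  grids <- as_grid_list(grids)
  if (!is.numeric(density_per_cm2) || density_per_cm2 < 0) {
    stop("`density_per_cm2` must be >= 0", call. = FALSE)
  }
  if (!inherits(mix, "taxon_mix")) mix <- taxon_mix(mix)
  if (is.null(radius_model)) {
    radius_model <- function(n) stats::rlnorm(n, meanlog = log(12),
                                              sdlog = 0.35)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(names(grids), function(mid) {
    g <- grids[[mid]]
    ext <- montage_extent(g)
    n <- stats::rpois(1L, density_per_cm2 * ext$area_cm2_exact)
    if (n == 0L) {
      return(tibble::tibble(
        specimen_id = character(0), montage = character(0),
        x_um = numeric(0), y_um = numeric(0), radius_um = numeric(0),
        taxon = character(0), identifiable = logical(0)
      ))
    }
    taxon <- sample(names(mix), n, replace = TRUE, prob = as.numeric(mix))
    tibble::tibble(
      specimen_id = sprintf("sp_%s_%05d", mid, seq_len(n)),
      montage = mid,
      x_um = stats::runif(n, 0, ext$width_um_exact),
      y_um = stats::runif(n, 0, ext$height_um_exact),
      radius_um = radius_model(n),
      taxon = taxon,
      identifiable = taxon != "indeterminable"
    )
  })
  dplyr::bind_rows(out)
}

as_grid_list <- function(grids) {
  if (is_tile_grid(grids)) grids <- list(grids)
  if (!is.list(grids) || length(grids) == 0L ||
      !all(vapply(grids, is_tile_grid, logical(1)))) {
    stop("`grids` must be a `tile_grid` or non-empty list of them",
         call. = FALSE)
  }
  if (is.null(names(grids)) || any(!nzchar(names(grids)))) {
    names(grids) <- sprintf("m%d", seq_along(grids))
  }
  grids
}

#' Per-tile ground-truth annotations, including overlap duplicates
#'
#' Each specimen yields one annotation in every tile whose footprint contains
#' its centre (via [tiles_covering()]), so a specimen sitting in an overlap
#' strip appears in two tiles and one at a four-tile corner appears in four —
#' the duplication an overlap-aware census must undo. The per-detection
#' `position_class` is `"edge"` when the centre lies in the tile's overlap
#' band (width `overlap_frac` times the tile extent on each side that has a
#' neighbour), `"middle"` otherwise.
#'
#' @param specimens Output of [generate_specimens()].
#' @param grids The grids the specimens were generated on.
#' @return A [tibble::tibble()]: `image_id`, `montage`, `col`, `row`,
#'   `specimen_id`, `x_local_um`, `y_local_um`, `position_class`, `taxon`,
#'   `identifiable`.
#' @export
truth_annotations <- function(specimens, grids) {
  grids <- as_grid_list(grids)
  if (nrow(specimens) == 0L) {
    return(tibble::tibble(
      image_id = character(0), montage = character(0),
      col = integer(0), row = integer(0), specimen_id = character(0),
      x_local_um = numeric(0), y_local_um = numeric(0),
      position_class = character(0), taxon = character(0),
      identifiable = logical(0)
    ))
  }
  rows <- vector("list", nrow(specimens))
  for (i in seq_len(nrow(specimens))) {
    sp <- specimens[i, ]
    g <- grids[[sp$montage]]
    if (is.null(g)) stop("unknown montage: ", sp$montage, call. = FALSE)
    tl <- tiles_covering(g, sp$x_um, sp$y_um)
    if (nrow(tl) == 0L) {
      stop("specimen outside montage extent: ", sp$specimen_id, call. = FALSE)
    }
    loc <- global_to_tile_local(g, tl$col, tl$row, sp$x_um, sp$y_um)
    ext <- tile_extent_um(g)
    band <- g$overlap_frac * ext
    in_band <-
      (tl$col > 0L & loc$x_um <= band[["x"]]) |
      (tl$col < g$n_cols - 1L & loc$x_um >= ext[["x"]] - band[["x"]]) |
      (tl$row > 0L & loc$y_um <= band[["y"]]) |
      (tl$row < g$n_rows - 1L & loc$y_um >= ext[["y"]] - band[["y"]])
    rows[[i]] <- tibble::tibble(
      image_id = image_id(sp$montage, tl$col, tl$row),
      montage = sp$montage,
      col = tl$col, row = tl$row,
      specimen_id = sp$specimen_id,
      x_local_um = loc$x_um, y_local_um = loc$y_um,
      position_class = ifelse(in_band, "edge", "middle"),
      taxon = sp$taxon,
      identifiable = sp$identifiable
    )
  }
  dplyr::bind_rows(rows)
}

# image-level truth answer for the position question
position_answer <- function(classes) {
  u <- unique(classes)
  if (length(u) == 1L) u else "middle_and_edge"
}

majority_label <- function(labels) {
  tab <- table(labels)
  names(tab)[which.max(tab)]
}

#' Simulate sequential volunteer transcriptions
#'
#' Serves every image of every montage to up to `max_views` distinct
#' volunteers sampled with probability proportional to `activity_weight`.
#' Each served volunteer answers the five-question template from the image's
#' ground truth through their error model: each present specimen is detected
#' with probability `sensitivity`; an empty view is reported as containing a
#' fossil with probability `false_positive_rate`; the stated count is off by
#' one with probability `count_error_rate` (clamped to `[1, count_max]`); the
#' taxon name is drawn from the naming-confusion matrix; the focus answer is
#' wrong with probability `focus_error_rate`. Serving of an image stops as
#' soon as the consensus engine closes it (see [aggregate_image()]) or
#' `max_views` responses have been collected; skipped views produce no
#' response and do not count toward the quorum.
#'
#' @param annotations Ground-truth annotations from [truth_annotations()]
#'   (may have zero rows for an empty field).
#' @param grids The montage grids (defines the image universe).
#' @param profiles A [volunteer_profiles()] table.
#' @param quorum,max_views Consensus parameters (defaults 3 and 4).
#' @param count_max Upper bound of the count drop-down; larger detected
#'   counts are binned to this value (default 10).
#' @param seed Optional integer seed.
#' @return A [tibble::tibble()] of responses in served order (columns of
#'   [validate_responses()]).
#' @export
simulate_transcriptions <- function(annotations, grids, profiles,
                                    quorum = 3, max_views = 4,
                                    count_max = 10, seed = NULL) {
  grids <- as_grid_list(grids)
  if (nrow(profiles) == 0L) stop("`profiles` must be non-empty", call. = FALSE)
  if (quorum > max_views) stop("`quorum` must be <= `max_views`", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  confusion <- attr(profiles, "name_confusion")
  if (is.null(confusion)) {
    stop("`profiles` lacks the `name_confusion` attribute", call. = FALSE)
  }

  ids <- unlist(lapply(names(grids), function(mid) {
    all_image_ids(grids[[mid]], mid)
  }), use.names = FALSE)
  n_img <- length(ids)
  mv <- as.integer(max_views)
  n_vol <- nrow(profiles)

  # serve up to max_views distinct volunteers per image (extras drawn when
  # skipping is possible, so skips can be replaced by later volunteers)
  any_skip <- any(profiles$skip_rate > 0)
  n_draw <- min(n_vol, if (any_skip) 2L * mv else mv)
  vol_idx <- matrix(NA_integer_, n_img, n_draw)
  w <- profiles$activity_weight
  for (i in seq_len(n_img)) {
    vol_idx[i, ] <- sample.int(n_vol, n_draw, prob = w)
  }
  if (any_skip) {
    keep <- matrix(stats::runif(n_img * n_draw) >=
                     profiles$skip_rate[vol_idx], n_img, n_draw)
    vol_idx <- t(apply(cbind(vol_idx, keep), 1L, function(z) {
      v <- z[seq_len(n_draw)][as.logical(z[-seq_len(n_draw)])]
      length(v) <- mv
      v
    }))
  } else {
    vol_idx <- vol_idx[, seq_len(mv), drop = FALSE]
  }

  # image-level truth summary
  truth <- list()
  if (nrow(annotations) > 0L) {
    truth <- split(annotations, annotations$image_id)
  }
  fossil_ids <- names(truth)
  fossil_pos <- match(fossil_ids, ids)
  if (anyNA(fossil_pos)) {
    stop("annotations refer to images outside the grids", call. = FALSE)
  }
  img_truth_n <- integer(n_img)
  img_truth_n[fossil_pos] <- vapply(truth, nrow, integer(1))

  # candidate answers for every image x view (independent of serving order,
  # so pre-generating and truncating at closure is distribution-identical)
  focus <- matrix("in_focus", n_img, mv)
  occurrence <- matrix("no_fossil", n_img, mv)
  count <- matrix(0L, n_img, mv)
  position <- matrix("none", n_img, mv)
  name <- matrix("none", n_img, mv)

  served <- !is.na(vol_idx)
  sens <- matrix(profiles$sensitivity[vol_idx], n_img, mv)
  fpr <- matrix(profiles$false_positive_rate[vol_idx], n_img, mv)
  cer <- matrix(profiles$count_error_rate[vol_idx], n_img, mv)
  fer <- matrix(profiles$focus_error_rate[vol_idx], n_img, mv)
  sens[!served] <- 0
  fpr[!served] <- 0
  cer[!served] <- 0
  fer[!served] <- 0

  focus[stats::runif(n_img * mv) < fer] <- "out_of_focus"

  taxa_out <- colnames(confusion)
  fp_name_prob <- c(rep(0.5 / (length(taxa_out) - 1L),
                        length(taxa_out) - 1L), 0.5)

  empty <- img_truth_n == 0L
  # false positives on empty images
  fp <- matrix(FALSE, n_img, mv)
  fp[empty, ] <- stats::runif(sum(empty) * mv) < fpr[empty, , drop = FALSE]
  n_fp <- sum(fp)
  if (n_fp > 0L) {
    occurrence[fp] <- "fossil"
    cnt <- rep(1L, n_fp)
    err <- stats::runif(n_fp) < cer[fp]
    cnt[err] <- cnt[err] + sample(c(-1L, 1L), sum(err), replace = TRUE)
    count[fp] <- pmin(pmax(cnt, 1L), count_max)
    position[fp] <- sample(c("middle", "edge", "middle_and_edge"), n_fp,
                           replace = TRUE, prob = c(0.6, 0.3, 0.1))
    name[fp] <- sample(taxa_out, n_fp, replace = TRUE, prob = fp_name_prob)
  }

  # fossil images: per-specimen detection per view
  for (iid in fossil_ids) {
    i <- match(iid, ids)
    ann <- truth[[iid]]
    for (v in seq_len(mv)) {
      if (is.na(vol_idx[i, v])) next
      det <- stats::runif(nrow(ann)) < sens[i, v]
      k <- sum(det)
      if (k == 0L) next # all specimens overlooked in this view
      occurrence[i, v] <- "fossil"
      kk <- k
      if (stats::runif(1) < cer[i, v]) {
        kk <- kk + sample(c(-1L, 1L), 1L)
      }
      count[i, v] <- pmin(pmax(kk, 1L), count_max)
      position[i, v] <- position_answer(ann$position_class[det])
      true_lab <- majority_label(ann$taxon[det])
      name[i, v] <- sample(taxa_out, 1L, prob = confusion[true_lab, ])
    }
  }

  n_avail <- rowSums(!is.na(vol_idx))

  # sequential closure: first t in quorum..mv with a quorum-identical subset
  key <- matrix(paste(focus, occurrence, count, position, name,
                      sep = key_sep), n_img, mv)
  key[is.na(vol_idx)] <- NA_character_
  closed_at <- rep(NA_integer_, n_img)
  for (t in quorum:mv) {
    open <- which(is.na(closed_at) & n_avail >= t)
    if (!length(open)) next
    sub <- key[open, seq_len(t), drop = FALSE]
    for (j in seq_len(t)) {
      cnt_j <- rowSums(sub == sub[, j])
      hit <- cnt_j >= quorum & is.na(closed_at[open])
      if (any(hit)) closed_at[open[hit]] <- t
    }
  }
  n_used <- ifelse(is.na(closed_at), n_avail, closed_at)

  take <- which(col(key) <= matrix(n_used, n_img, mv) & !is.na(vol_idx))
  ord <- order(row(key)[take], col(key)[take])
  take <- take[ord]
  tibble::tibble(
    image_id = ids[row(key)[take]],
    volunteer_id = profiles$volunteer_id[vol_idx[take]],
    order_index = col(key)[take],
    focus = focus[take],
    occurrence = occurrence[take],
    count = as.integer(count[take]),
    position = position[take],
    name = name[take]
  )
}
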
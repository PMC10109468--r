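# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately implemented by a different route than the package code it
# checks.

# the acquisition geometry of the survey the package emulates
paper_grid <- function() {
  tile_grid(60, 60, 6144, 4090, fov_width_um = 120, overlap_frac = 0.125,
            dwell_s_per_image = 8)
}

# compact response builder: one row per call
resp <- function(image_id, order_index, occurrence,
                 focus = "in_focus", count = if (occurrence == "fossil") 1L else 0L,
                 position = if (occurrence == "fossil") "middle" else "none",
                 name = if (occurrence == "fossil") "taxA" else "none",
                 volunteer_id = paste0("v", order_index)) {
  tibble::tibble(
    image_id = image_id, volunteer_id = volunteer_id,
    order_index = as.integer(order_index), focus = focus,
    occurrence = occurrence, count = as.integer(count),
    position = position, name = name
  )
}

resp_stream <- function(image_id, ...) {
  rows <- list(...)
  dplyr::bind_rows(Map(function(r, i) {
    do.call(resp, c(list(image_id = image_id, order_index = i), r))
  }, rows, seq_along(rows)))
}

# ---- serving-process oracle -------------------------------------------------
# Literal replay of the serving process: after each arrival, enumerate every
# quorum-sized subset of the responses so far and test pairwise identity
# field by field. Independent of the key-hashing scan in the package.

same_answers <- function(a, b) {
  all(vapply(c("focus", "occurrence", "count", "position", "name"),
             function(f) identical(a[[f]], b[[f]]), logical(1)))
}

oracle_aggregate <- function(responses, quorum = 3, max_views = 4) {
  responses <- responses[order(responses$order_index), , drop = FALSE]
  n <- nrow(responses)
  for (t in seq_len(n)) {
    if (t < quorum) next
    subsets <- utils::combn(t, quorum, simplify = FALSE)
    for (s in subsets) {
      pairs <- utils::combn(s, 2, simplify = FALSE)
      ok <- all(vapply(pairs, function(p) {
        same_answers(responses[p[1], ], responses[p[2], ])
      }, logical(1)))
      if (ok) {
        occ <- responses$occurrence[s[1]]
        category <- if (occ == "fossil") "AGREEMENT_FOSSIL" else "AGREEMENT_NO_FOSSIL"
        disputed <- category == "AGREEMENT_NO_FOSSIL" &&
          any(responses$occurrence[seq_len(t)] == "fossil")
        return(list(category = category, disputed = disputed,
                    n_responses = t))
      }
    }
  }
  list(
    category = if (n >= max_views) "NO_AGREEMENT" else "PENDING",
    disputed = FALSE, n_responses = n
  )
}

# ---- all-pairs union-find oracle for single-linkage dedup -------------------

uf_clusters <- function(x, y, eps) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= eps) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# cluster partitions as canonical sets of member indices
partition_sets <- function(labels) {
  unname(lapply(split(seq_along(labels), labels), sort))
}

same_partition <- function(a, b) {
  setequal(lapply(partition_sets(a), paste, collapse = ","),
           lapply(partition_sets(b), paste, collapse = ","))
}

# ---- brute-force tile scan --------------------------------------------------

scan_tiles_covering <- function(grid, x, y) {
  fp <- tile_footprint(grid)
  step_x <- fp$width_um * (1 - grid$overlap_frac)
  step_y <- fp$height_um * (1 - grid$overlap_frac)
  hits <- list()
  for (col in 0:(grid$n_cols - 1)) {
    for (row in 0:(grid$n_rows - 1)) {
      x0 <- col * step_x
      y0 <- row * step_y
      if (x >= x0 - 1e-9 && x <= x0 + fp$width_um + 1e-9 &&
          y >= y0 - 1e-9 && y <= y0 + fp$height_um + 1e-9) {
        hits[[length(hits) + 1L]] <- c(col, row)
      }
    }
  }
  if (!length(hits)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, hits)
}

# perfect volunteers: always right, never skip
perfect_profiles <- function(n = 10, seed = 1) {
  volunteer_profiles(n = n, sensitivity = 1, false_positive_rate = 0,
                     count_error_rate = 0, focus_error_rate = 0,
                     name_accuracy = 1, unknown_rate = 0, seed = seed)
}
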
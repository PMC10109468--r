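test_that("taxon mixes validate and the default mirrors the survey mix", {
  expect_error(taxon_mix(c(a = 0.5, b = 0.5)), "indeterminable")
  expect_error(taxon_mix(c(a = 0.7, indeterminable = 0.7)), "sum to 1")
  mix <- default_taxon_mix()
  expect_s3_class(mix, "taxon_mix")
  expect_equal(sum(mix), 1)
  expect_equal(unname(mix[["indeterminable"]]), 83 / 383)
  # identifiable fractions keep their 44/20/9 ratios
  ident <- mix[mix_taxa(mix)] / (1 - mix[["indeterminable"]])
  expect_equal(unname(ident[["Nothofagidites"]]), 0.44)
  expect_equal(unname(ident[["fungal_spore"]]), 0.20)
  expect_equal(unname(ident[["fern_moss_spore"]]), 0.09)
})

test_that("specimen fields are Poisson with the requested density", {
  g <- paper_grid()
  expect_equal(nrow(generate_specimens(g, 0, seed = 1)), 0L)
  expect_error(generate_specimens(g, -1), ">= 0")

  s1 <- generate_specimens(g, 207, seed = 99)
  s2 <- generate_specimens(g, 207, seed = 99)
  expect_identical(s1, s2)
  ext <- montage_extent(g)
  expect_true(all(s1$x_um >= 0 & s1$x_um <= ext$width_um_exact))
  expect_true(all(s1$y_um >= 0 & s1$y_um <= ext$height_um_exact))

  # Monte-Carlo mean of the whole-survey count: lambda = 207 * exact area of
  # seven montages (~385); the observed 383 specimens sit well inside
  grids <- rep(list(g), 7)
  lambda <- 207 * dataset_totals(grids)$total_area_cm2_exact
  set.seed(123)
  counts <- replicate(500, nrow(generate_specimens(grids, 207)))
  se <- sqrt(lambda / 500)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  expect_lt(abs(lambda - 383), 3 * sqrt(lambda))
})

test_that("truth annotations duplicate specimens across overlap tiles", {
  g <- tile_grid(3, 3, 1000, 1000, 120, 0.125)
  grids <- list(m1 = g)
  sp <- function(x, y, id = "s1") tibble::tibble(
    specimen_id = id, montage = "m1", x_um = x, y_um = y, radius_um = 10,
    taxon = "Nothofagidites", identifiable = TRUE
  )
  # non-overlap core: one annotation, middle
  a <- truth_annotations(sp(160, 160), grids)
  expect_equal(nrow(a), 1L)
  expect_equal(a$position_class, "middle")
  # one-axis strip: two annotations, edge in both
  a <- truth_annotations(sp(110, 160), grids)
  expect_equal(nrow(a), 2L)
  expect_equal(a$position_class, rep("edge", 2))
  expect_setequal(a$col, c(0L, 1L))
  # four-tile corner: four annotations
  a <- truth_annotations(sp(110, 110), grids)
  expect_equal(nrow(a), 4L)
  expect_equal(a$position_class, rep("edge", 4))

  # property: annotation count equals brute-force tile coverage; local
  # positions map back to the specimen
  set.seed(5)
  ext <- montage_extent(g)
  for (i in 1:40) {
    x <- runif(1, 0, ext$width_um_exact)
    y <- runif(1, 0, ext$height_um_exact)
    a <- truth_annotations(sp(x, y), grids)
    expect_equal(nrow(a), nrow(scan_tiles_covering(g, x, y)))
    glob <- local_to_global(g, a$col, a$row, a$x_local_um, a$y_local_um)
    expect_equal(glob$x_um, rep(x, nrow(a)))
    expect_equal(glob$y_um, rep(y, nrow(a)))
  }
})

test_that("perfect volunteers close every image after exactly the quorum", {
  g <- tile_grid(6, 6, 1000, 1000, 120, 0.125)
  grids <- list(m1 = g)
  sp <- generate_specimens(grids, 3000, seed = 21)
  ann <- truth_annotations(sp, grids)
  responses <- simulate_transcriptions(ann, grids, perfect_profiles(),
                                       seed = 22)
  per_image <- table(responses$image_id)
  expect_equal(length(per_image), 36L)
  expect_true(all(per_image == 3))
  v <- consensus_verdicts(responses)
  expect_true(all(v$category %in% c("AGREEMENT_FOSSIL",
                                    "AGREEMENT_NO_FOSSIL")))
  expect_false(any(v$disputed))
  # fossil verdicts exactly where the field has specimens
  expect_setequal(v$image_id[v$category == "AGREEMENT_FOSSIL"],
                  unique(ann$image_id))
})

test_that("forced false positives never validate as fossil-free", {
  g <- tile_grid(4, 4, 1000, 1000, 120, 0.125)
  grids <- list(m1 = g)
  prof <- volunteer_profiles(n = 30, false_positive_rate = 1, seed = 3)
  empty <- truth_annotations(
    generate_specimens(grids, 0, seed = 1), grids)
  responses <- simulate_transcriptions(empty, grids, prof, seed = 4)
  v <- consensus_verdicts(responses)
  expect_true(all(v$category %in% c("AGREEMENT_FOSSIL", "NO_AGREEMENT")))
})

test_that("the simulator is deterministic and respects serving bounds", {
  g <- tile_grid(8, 8, 1000, 1000, 120, 0.125)
  grids <- list(m1 = g)
  sp <- generate_specimens(grids, 500, seed = 31)
  ann <- truth_annotations(sp, grids)
  prof <- volunteer_profiles(n = 40, seed = 32)
  r1 <- simulate_transcriptions(ann, grids, prof, seed = 33)
  r2 <- simulate_transcriptions(ann, grids, prof, seed = 33)
  expect_identical(r1, r2)
  per_image <- table(r1$image_id)
  expect_true(all(per_image >= 3 & per_image <= 4))
  expect_lte(nrow(r1), 64 * 4)
  expect_error(simulate_transcriptions(ann, grids, prof, quorum = 5,
                                       max_views = 4), "quorum")
  # volunteers are distinct within an image
  dup <- tapply(r1$volunteer_id, r1$image_id,
                function(v) any(duplicated(v)))
  expect_false(any(dup))
})

test_that("activity weights are heavy-tailed: the top decile dominates", {
  prof <- volunteer_profiles(n = 271, seed = 8)
  g <- tile_grid(20, 20, 1000, 1000, 120, 0.125)
  grids <- list(m1 = g)
  responses <- simulate_transcriptions(
    truth_annotations(generate_specimens(grids, 207, seed = 9), grids),
    grids, prof, seed = 10)
  per_vol <- sort(table(responses$volunteer_id), decreasing = TRUE)
  top <- ceiling(0.1 * nrow(prof))
  share <- sum(per_vol[seq_len(min(top, length(per_vol)))]) / nrow(responses)
  expect_gt(share, 0.5) # qualitative match to the observed 85%/10% skew
})

test_that("calibrated defaults reproduce the observed review-queue load", {
  g <- paper_grid()
  grids <- list(m1 = g)
  fracs <- vapply(1:10, function(s) {
    sp <- generate_specimens(grids, 207, seed = 1000 + s)
    ann <- truth_annotations(sp, grids)
    prof <- volunteer_profiles(seed = 2000 + s)
    v <- consensus_verdicts(simulate_transcriptions(ann, grids, prof,
                                                    seed = 3000 + s))
    fl <- flow_report(v)
    fl$n_review_queue / fl$n_images
  }, numeric(1))
  # observed load: 4192 of 25,200 images needed an expert (~16.6%)
  expect_lt(abs(mean(fracs) - 4192 / 25200), 0.05)
})

test_that("better volunteers shrink the expected review queue", {
  g <- tile_grid(20, 20, 1000, 1000, 120, 0.125)
  grids <- list(m1 = g)
  queue_size <- function(prof, s) {
    ann <- truth_annotations(generate_specimens(grids, 207, seed = s), grids)
    v <- consensus_verdicts(simulate_transcriptions(ann, grids, prof,
                                                    seed = s + 1))
    length(build_review_queue(v))
  }
  seeds <- c(41, 43, 45)
  default_q <- vapply(seeds, function(s) {
    queue_size(volunteer_profiles(seed = s), s)
  }, numeric(1))
  sharp_q <- vapply(seeds, function(s) {
    queue_size(volunteer_profiles(false_positive_rate = 0.005,
                                  focus_error_rate = 0.005,
                                  sensitivity = 0.99, seed = s), s)
  }, numeric(1))
  expect_lt(mean(sharp_q), mean(default_q))
})
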
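test_that("the decision tree validates, disputes and fails agreement as documented", {
  # three identical no-fossil responses validate cleanly
  v <- aggregate_image(resp_stream("i1",
    list(occurrence = "no_fossil"), list(occurrence = "no_fossil"),
    list(occurrence = "no_fossil")))
  expect_equal(v$category, "AGREEMENT_NO_FOSSIL")
  expect_false(v$disputed)
  expect_equal(v$n_responses, 3L)
  expect_equal(v$fossil_sublabel, "none")

  # a fossil report before three no-fossil agreements flags a dispute
  v <- aggregate_image(resp_stream("i2",
    list(occurrence = "no_fossil"), list(occurrence = "fossil"),
    list(occurrence = "no_fossil"), list(occurrence = "no_fossil")))
  expect_equal(v$category, "AGREEMENT_NO_FOSSIL")
  expect_true(v$disputed)
  expect_equal(v$n_responses, 4L)

  # three identical fossil responses validate with a pollen/spore sublabel
  v <- aggregate_image(resp_stream("i3",
    list(occurrence = "fossil"), list(occurrence = "fossil"),
    list(occurrence = "fossil")))
  expect_equal(v$category, "AGREEMENT_FOSSIL")
  expect_equal(v$fossil_sublabel, "pollen_or_spore")
  v <- aggregate_image(resp_stream("i3u",
    list(occurrence = "fossil", name = "unknown"),
    list(occurrence = "fossil", name = "unknown"),
    list(occurrence = "fossil", name = "unknown")))
  expect_equal(v$fossil_sublabel, "unknown")

  # four responses, no three fully identical: counts 1,2,1,1 but one of the
  # count-1 responses differs in position
  v <- aggregate_image(resp_stream("i4",
    list(occurrence = "fossil", count = 1),
    list(occurrence = "fossil", count = 2),
    list(occurrence = "fossil", count = 1, position = "edge"),
    list(occurrence = "fossil", count = 1)))
  expect_equal(v$category, "NO_AGREEMENT")
  expect_equal(oracle_aggregate(resp_stream("i4",
    list(occurrence = "fossil", count = 1),
    list(occurrence = "fossil", count = 2),
    list(occurrence = "fossil", count = 1, position = "edge"),
    list(occurrence = "fossil", count = 1)))$category, "NO_AGREEMENT")
})

test_that("truncated streams are pending; malformed streams error", {
  v <- aggregate_image(resp_stream("p1",
    list(occurrence = "no_fossil"), list(occurrence = "no_fossil")))
  expect_equal(v$category, "PENDING")
  expect_equal(v$n_responses, 2L)

  too_many <- resp_stream("e1", list(occurrence = "no_fossil"),
    list(occurrence = "no_fossil"), list(occurrence = "fossil", count = 2),
    list(occurrence = "fossil"), list(occurrence = "fossil", count = 3))
  expect_error(aggregate_image(too_many), "max_views")
  dup <- resp_stream("e2", list(occurrence = "no_fossil"),
                     list(occurrence = "no_fossil"))
  dup$order_index <- c(1L, 1L)
  expect_error(aggregate_image(dup), "order_index")
  expect_error(aggregate_image(resp_stream("e3", list(occurrence = "fossil")),
                               quorum = 5, max_views = 4), "quorum")
  bad <- resp_stream("e4", list(occurrence = "no_fossil"))
  bad$count <- 2L
  expect_error(aggregate_image(bad), "no_fossil")
})

test_that("disagreement fields are the exact set of dissenting questions", {
  s <- resp_stream("d1",
    list(occurrence = "fossil"), list(occurrence = "fossil"),
    list(occurrence = "fossil"))
  expect_equal(disagreement_fields(s), character(0))

  s2 <- s
  s2$count <- c(1L, 2L, 1L)
  expect_equal(disagreement_fields(s2), "count")

  s3 <- s
  s3$count <- c(1L, 2L, 1L)
  s3$name <- c("taxA", "taxB", "taxA")
  expect_equal(disagreement_fields(s3), c("count", "name"))

  expect_error(disagreement_fields(s[1, ]), "at least 2")
})

test_that("dispute flagging honours order-aware vs order-free modes", {
  # fossil report arrives after the closing no-fossil quorum would have
  # closed the image, so order-aware scanning cannot see it
  s <- resp_stream("o1",
    list(occurrence = "no_fossil"), list(occurrence = "no_fossil"),
    list(occurrence = "no_fossil"), list(occurrence = "fossil"))
  aware <- aggregate_image(s, order_aware = TRUE)
  free <- aggregate_image(s, order_aware = FALSE)
  expect_equal(aware$category, "AGREEMENT_NO_FOSSIL")
  expect_false(aware$disputed)
  expect_true(free$disputed)
})

test_that("matching can be restricted to the occurrence question", {
  s <- resp_stream("m1",
    list(occurrence = "fossil", count = 1),
    list(occurrence = "fossil", count = 2),
    list(occurrence = "fossil", count = 3))
  expect_equal(aggregate_image(s)$category, "PENDING")
  expect_equal(aggregate_image(s, match_fields = "occurrence")$category,
               "AGREEMENT_FOSSIL")
})

test_that("verdicts are invariant to volunteer identity", {
  s <- resp_stream("v1",
    list(occurrence = "fossil"), list(occurrence = "no_fossil"),
    list(occurrence = "fossil"), list(occurrence = "fossil"))
  v1 <- aggregate_image(s)
  s$volunteer_id <- rev(s$volunteer_id)
  expect_equal(aggregate_image(s), v1)
})

test_that("the vectorised engine matches per-image aggregation on random streams", {
  set.seed(101)
  answers <- list(
    list(occurrence = "no_fossil"),
    list(occurrence = "no_fossil", focus = "out_of_focus"),
    list(occurrence = "fossil", count = 1),
    list(occurrence = "fossil", count = 2, name = "taxB"),
    list(occurrence = "fossil", count = 1, position = "edge")
  )
  for (params in list(c(3, 4), c(2, 3), c(3, 5))) {
    quorum <- params[1]; mv <- params[2]
    streams <- lapply(1:60, function(i) {
      n <- sample(1:mv, 1)
      do.call(resp_stream, c(list(sprintf("img%03d", i)),
                             sample(answers, n, replace = TRUE)))
    })
    all_resp <- dplyr::bind_rows(streams)
    vec <- consensus_verdicts(all_resp, quorum = quorum, max_views = mv)
    ref <- dplyr::bind_rows(lapply(streams, aggregate_image,
                                   quorum = quorum, max_views = mv))
    ref <- ref[order(ref$image_id), ]
    expect_equal(vec, ref)
  }
})

test_that("flow accounting reconciles and reproduces a hand-counted set", {
  streams <- list(
    resp_stream("a", list(occurrence = "no_fossil"),
                list(occurrence = "no_fossil"), list(occurrence = "no_fossil")),
    resp_stream("b", list(occurrence = "no_fossil"),
                list(occurrence = "no_fossil"), list(occurrence = "no_fossil")),
    resp_stream("c", list(occurrence = "fossil"), list(occurrence = "no_fossil"),
                list(occurrence = "no_fossil"), list(occurrence = "no_fossil")),
    resp_stream("d", list(occurrence = "fossil"), list(occurrence = "fossil"),
                list(occurrence = "fossil")),
    resp_stream("e", list(occurrence = "fossil", count = 1),
                list(occurrence = "fossil", count = 2),
                list(occurrence = "no_fossil"), list(occurrence = "fossil", count = 3)),
    resp_stream("f", list(occurrence = "fossil", name = "taxA"),
                list(occurrence = "fossil", name = "taxB"),
                list(occurrence = "no_fossil"), list(occurrence = "fossil", count = 2))
  )
  fl <- flow_report(consensus_verdicts(dplyr::bind_rows(streams)))
  expect_equal(fl$n_images, 6L)
  expect_equal(fl$n_agreement_no_fossil, 3L)
  expect_equal(fl$n_disputed, 1L)
  expect_equal(fl$n_agreement_fossil, 1L)
  expect_equal(fl$n_no_agreement, 2L)
  expect_equal(fl$n_review_queue, 4L)
  # structural identities
  expect_equal(fl$n_agreement, fl$n_agreement_no_fossil + fl$n_agreement_fossil)
  expect_equal(fl$n_images, fl$n_agreement + fl$n_no_agreement)
  expect_lte(fl$n_disputed, fl$n_agreement_no_fossil)

  # all no-fossil, no disputes: empty queue
  quiet <- dplyr::bind_rows(lapply(1:4, function(i) {
    resp_stream(paste0("q", i), list(occurrence = "no_fossil"),
                list(occurrence = "no_fossil"), list(occurrence = "no_fossil"))
  }))
  expect_equal(flow_report(consensus_verdicts(quiet))$n_review_queue, 0L)
})

test_that("no-agreement images decompose by disagreement reason", {
  streams <- dplyr::bind_rows(
    resp_stream("x", list(occurrence = "fossil", count = 1),
                list(occurrence = "fossil", count = 2),
                list(occurrence = "fossil", count = 3),
                list(occurrence = "fossil", count = 4)),
    resp_stream("y", list(occurrence = "fossil", name = "taxA", count = 1),
                list(occurrence = "fossil", name = "taxB", count = 2),
                list(occurrence = "fossil", name = "taxC", count = 3),
                list(occurrence = "fossil", name = "taxD", count = 4))
  )
  bk <- disagreement_breakdown(consensus_verdicts(streams))
  expect_setequal(bk$disagreement_fields, c("count", "count,name"))
  expect_equal(sum(bk$n), 2L)
})
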
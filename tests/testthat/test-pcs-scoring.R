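test_that("compute_pcs is the weighted average over non-zero template edges", {
  ev <- edge_vector(c(0.5, -0.2, 0.1), subject_id = "s1",
                    parcel_labels = paste0("p", 1:3))
  tpl <- tiny_template(c(2, 0, -1))
  res <- compute_pcs(ev, tpl)
  expect_equal(res$n_nonzero, 2L)
  expect_equal(res$score, 0.45, tolerance = 1e-15)

  # zero connectivity scores zero
  expect_equal(compute_pcs(edge_vector(rep(0, 3), "z",
                                       parcel_labels = paste0("p", 1:3)),
                           tpl)$score, 0)

  # positive self-alignment: edges proportional to the weights themselves
  w <- tiny_template(c(0.8, -0.4, 0.2))
  self <- edge_vector(c(0.8, -0.4, 0.2), "self", parcel_labels = paste0("p", 1:3))
  expect_gt(compute_pcs(self, w)$score, 0)

  # all-zero template is rejected at construction already
  expect_error(tiny_template(c(0, 0, 0)), "non-zero")
})

test_that("vectorized scoring matches the naive double-loop oracle", {
  for (seed in 1:20) {
    p <- 20L
    fc <- random_fc(p, seed)
    tpl <- random_template(p, seed + 1000L)
    tpl$parcel_labels <- fc$parcel_labels
    names(tpl$network_partition) <- fc$parcel_labels
    wm <- matrix(0, p, p)
    wm[tpl$edge_index] <- tpl$weights
    wm <- wm + t(wm)
    got <- compute_pcs(vectorize_fc(fc), tpl)$score
    expect_lt(abs(got - naive_pcs(fc$values, wm)), 1e-12)
  }
})

test_that("scores ignore connectivity at zero-weight edges bit-exactly", {
  tpl <- random_template(12, 7, frac_nonzero = 0.4)
  ev <- withr::with_seed(8, edge_vector(runif(n_edges(12), -1, 1), "s",
                                        parcel_labels = tpl$parcel_labels))
  ref <- compute_pcs(ev, tpl)$score
  zero_idx <- which(tpl$weights == 0)
  expect_gt(length(zero_idx), 0)
  for (seed in 1:25) {
    pert <- ev
    pert$values[zero_idx] <- withr::with_seed(seed,
                                              runif(length(zero_idx), -1, 1))
    expect_identical(compute_pcs(pert, tpl)$score, ref)
  }
})

test_that("scoring is linear and monotone along the template direction", {
  tpl <- random_template(10, 3)
  lbl <- tpl$parcel_labels
  e1 <- withr::with_seed(11, edge_vector(runif(n_edges(10), -1, 1), "a",
                                         parcel_labels = lbl))
  e2 <- withr::with_seed(12, edge_vector(runif(n_edges(10), -1, 1), "b",
                                         parcel_labels = lbl))
  for (ab in list(c(1, 1), c(2, -0.5), c(-3, 0.25))) {
    mix <- e1
    mix$values <- ab[1] * e1$values + ab[2] * e2$values
    expect_equal(compute_pcs(mix, tpl)$score,
                 ab[1] * compute_pcs(e1, tpl)$score +
                   ab[2] * compute_pcs(e2, tpl)$score,
                 tolerance = 1e-12)
  }
  # walking along sign(beta) strictly increases the score
  scores <- sapply(seq(0, 1, by = 0.25), function(lambda) {
    stepped <- e1
    stepped$values <- e1$values + lambda * sign(tpl$weights)
    compute_pcs(stepped, tpl)$score
  })
  expect_true(all(diff(scores) > 0))
})

test_that("atlas and degenerate-template contracts are enforced", {
  tpl <- tiny_template(c(1, 0, 0))
  ev_wrong_p <- edge_vector(rep(0.1, 6), "s")  # 4 parcels
  expect_error(compute_pcs(ev_wrong_p, tpl), "atlas mismatch")
  ev_wrong_labels <- edge_vector(c(0.1, 0.2, 0.3), "s",
                                 parcel_labels = c("q1", "q2", "q3"))
  expect_error(compute_pcs(ev_wrong_labels, tpl), "atlas mismatch")
  ev_na <- edge_vector(c(NA, 0.2, 0.3), "s", parcel_labels = paste0("p", 1:3))
  expect_error(compute_pcs(ev_na, tpl), "undefined")
})

test_that("edge-TSV and square-CSV template formats load identically", {
  tmp <- withr::local_tempdir()
  tpl <- random_template(8, 42, frac_nonzero = 0.5)
  write_template(tpl, file.path(tmp, "t.tsv"), format = "edge_tsv")
  write_template(tpl, file.path(tmp, "t2.csv"), format = "square_csv")
  from_edge <- load_template(file.path(tmp, "t.tsv"), format = "edge_tsv")
  from_square <- load_template(file.path(tmp, "t2.csv"), format = "square_csv")
  # text serialization carries 17 significant digits; near-exact round trip
  expect_equal(from_edge$weights, tpl$weights, tolerance = 1e-15)
  expect_equal(from_square$weights, from_edge$weights, tolerance = 1e-15)
  expect_identical(from_edge$network_partition, tpl$network_partition)
  expect_identical(from_edge$template_id, tpl$template_id)

  # direct read keeps canonical order regardless of row order in the file
  labels <- paste0("p", 1:3)
  writeLines(c("parcel_i\tparcel_j\tweight",
               "p2\tp3\t-1", "p1\tp2\t2"),
             file.path(tmp, "mini.tsv"))
  jsonlite::write_json(list(template_id = "mini", atlas_id = "a3",
                            parcel_labels = labels,
                            network_partition = as.list(
                              stats::setNames(rep("n1", 3), labels))),
                       file.path(tmp, "mini.json"), auto_unbox = TRUE)
  mini <- load_template(file.path(tmp, "mini.tsv"))
  expect_equal(mini$weights, c(2, 0, -1))
})

test_that("malformed template files raise validation errors", {
  tmp <- withr::local_tempdir()
  labels <- paste0("p", 1:3)
  sidecar <- list(template_id = "bad", atlas_id = "a3",
                  parcel_labels = labels,
                  network_partition = as.list(
                    stats::setNames(rep("n1", 3), labels)))

  dup <- file.path(tmp, "dup.tsv")
  writeLines(c("parcel_i\tparcel_j\tweight",
               "p1\tp2\t2", "p2\tp1\t3"), dup)
  jsonlite::write_json(sidecar, file.path(tmp, "dup.json"), auto_unbox = TRUE)
  expect_error(load_template(dup), "duplicate")

  unk <- file.path(tmp, "unk.tsv")
  writeLines(c("parcel_i\tparcel_j\tweight", "p1\tp9\t2"), unk)
  jsonlite::write_json(sidecar, file.path(tmp, "unk.json"), auto_unbox = TRUE)
  expect_error(load_template(unk), "p9")

  asym <- file.path(tmp, "asym.csv")
  writeLines(c("p1,p2,p3", "0,0.5,0", "0.4,0,0", "0,0,0"), asym)
  jsonlite::write_json(sidecar, file.path(tmp, "asym.json"), auto_unbox = TRUE)
  expect_error(load_template(asym, format = "square_csv"), "asymmetric")

  nop <- file.path(tmp, "nop.tsv")
  writeLines(c("parcel_i\tparcel_j\tweight", "p1\tp2\t2"), nop)
  jsonlite::write_json(sidecar[c("template_id", "atlas_id", "parcel_labels")],
                       file.path(tmp, "nop.json"), auto_unbox = TRUE)
  expect_error(load_template(nop), "network_partition")
})

test_that("batch_score matches singleton scoring and handles empty input", {
  tpl_a <- random_template(6, 1)
  tpl_b <- random_template(6, 2)
  tpl_b$template_id <- "tiny_b"
  lbl <- tpl_a$parcel_labels
  names(tpl_b$network_partition) <- tpl_b$parcel_labels <- lbl
  subs <- lapply(1:2, function(i) {
    withr::with_seed(i, edge_vector(runif(n_edges(6), -1, 1),
                                    paste0("s", i), parcel_labels = lbl))
  })
  tab <- batch_score(subs, list(tpl_a, tpl_b))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$subject_id, c("s1", "s1", "s2", "s2"))
  expect_identical(tab$pcs[1], compute_pcs(subs[[1]], tpl_a)$score)
  expect_identical(tab$pcs[4], compute_pcs(subs[[2]], tpl_b)$score)

  empty <- batch_score(list(), tpl_a)
  expect_equal(nrow(empty), 0L)

  # lenient mode skips a failing subject with a warning, strict aborts
  bad <- subs[[1]]
  bad$values[which(tpl_a$weights != 0)[1]] <- NA
  expect_error(batch_score(list(bad), tpl_a, policy = "strict"), "s1")
  lt <- NULL
  expect_warning(lt <- batch_score(list(bad, subs[[2]]), tpl_a,
                                   policy = "lenient"), "skipping")
  expect_true(is.na(lt$pcs[1]))
  expect_false(is.na(lt$pcs[2]))
})
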
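test_that("outcome dichotomization follows the 5-year rule", {
  expect_equal(derive_outcome(3.0, 1), "poor")
  expect_equal(derive_outcome(7.2, 0), "good")
  expect_equal(derive_outcome(2.1, 0), "excluded")
  expect_equal(derive_outcome(5.0, 0), "good")      # reached the threshold
  expect_equal(derive_outcome(6.0, 1), "good")      # event after threshold
  expect_equal(derive_outcome(c(1, 6), c(1, 1), threshold = 2),
               c("poor", "good"))
  expect_error(derive_outcome(-1, 1), "negative")
})

test_that("compendium round-trips through TSV and rejects bad input", {
  cmp <- tiny_compendium()
  ef <- tempfile(fileext = ".tsv"); af <- tempfile(fileext = ".tsv")
  write_compendium(cmp, ef, af)
  back <- read_compendium(ef, af)
  expect_equal(back$values, cmp$values)
  expect_equal(back$samples, cmp$samples)
  expect_equal(nrow(back$values), 6)
  expect_equal(ncol(back$values), 3)

  ann <- data.frame(sample_id = paste0("s", 1:5),
                    study = "st1", survival_time = 1, event = 1)
  vals <- tiny_compendium()$values
  expect_error(new_compendium(vals, ann), "s6")

  # non-numeric cell reported with coordinates
  tab <- read.delim(ef, check.names = FALSE)
  tab$GB[2] <- "oops"
  ef2 <- tempfile(fileext = ".tsv")
  write.table(tab, ef2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_compendium(ef2, af), "row 2.*GB")

  dup <- rbind(ann, ann[1, ])
  expect_error(new_compendium(vals[1:5, ][c(1:5), ],
                              dup), "duplicate")
})

test_that("recurrence-free survival takes precedence for labels", {
  cmp <- tiny_compendium()
  ann <- cmp$samples[, c("sample_id", "study", "survival_time", "event")]
  ann$rfs_time <- c(1, 1, 1, 1, 1, 1)
  ann$rfs_event <- 1
  cmp2 <- new_compendium(cmp$values, ann)
  expect_true(all(cmp2$samples$outcome == "poor"))
})

test_that("per-study quantile normalization equalizes within-study distributions", {
  cmp <- tiny_compendium()
  qn <- quantile_normalize_per_study(cmp)
  # hand computation: samples (1,6,1) and (2,5,1) etc. per study of 2
  st1 <- qn$values[1:2, ]
  expect_equal(sort(st1[1, ]), sort(st1[2, ]), ignore_attr = TRUE)

  # worked two-sample example: rows [1,2,3] and [4,5,6] -> mean quantiles
  vals <- matrix(c(1, 4, 2, 5, 3, 6), nrow = 2,
                 dimnames = list(c("a", "b"), c("g1", "g2", "g3")))
  ann <- data.frame(sample_id = c("a", "b"), study = "st",
                    survival_time = c(1, 1), event = c(1, 1))
  # need 2 studies for the class; add a second untouched study
  vals2 <- rbind(vals, c = c(9, 9, 9), d = c(7, 8, 9))
  ann2 <- rbind(ann, data.frame(sample_id = c("c", "d"), study = "st2",
                                survival_time = 1, event = 1))
  qn2 <- quantile_normalize_per_study(new_compendium(vals2, ann2))
  expect_equal(unname(qn2$values["a", ]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn2$values["b", ]), c(2.5, 3.5, 4.5))

  # idempotent fixed point
  qn3 <- quantile_normalize_per_study(qn2)
  expect_equal(qn3$values, qn2$values)

  # sample order within a study does not change per-sample output
  perm <- c(2, 1, 4, 3, 5, 6)
  cmp_p <- subset_compendium(cmp, samples = perm)
  qn_p <- quantile_normalize_per_study(cmp_p)
  expect_equal(qn_p$values[rownames(qn$values), ], qn$values)

  # single-sample study passes through with a warning
  vals3 <- vals2[c(1, 2, 3), ]
  ann3 <- ann2[1:3, ]
  expect_warning(q1 <- quantile_normalize_per_study(new_compendium(vals3, ann3)),
                 "single sample")
  expect_equal(q1$values["c", ], vals3["c", ])
})

test_that("network reading handles weighting, duplicates and malformed rows", {
  f <- tempfile()
  writeLines(c("a\tb", "b\tc", "a\tc"), f)
  tri <- read_network(f, weighting = "degree_average")
  expect_equal(tri$edges$weight, c(2, 2, 2))
  expect_error(read_network(f, weighting = "given"), "degree_average")

  writeLines(c("a\tb", "b\tc"), f)
  path2 <- read_network(f, weighting = "degree_average")
  expect_equal(path2$edges$weight, c(1.5, 1.5))

  writeLines(c("a\tb\t1", "b\ta\t3", "c\tc\t2"), f)
  expect_message(dd <- read_network(f), "self-loop")
  expect_equal(nrow(dd$edges), 1)
  expect_equal(dd$edges$weight, 3)        # duplicate keeps max weight

  writeLines(c("a\tb\t1", "justone"), f)
  expect_error(read_network(f), "line 2")

  net <- new_network(data.frame(gene_a = c("X", "Y"), gene_b = c("Y", "Z"),
                                weight = c(0.4, 0.9)))
  f2 <- tempfile()
  write_network(net, f2)
  expect_equal(read_network(f2)$edges, net$edges)
  # symbols are uppercased on ingestion so they match compendium gene ids
  writeLines("tp53\tbrca1\t1", f2)
  expect_equal(read_network(f2)$edges$gene_a, "BRCA1")
})

test_that("network thresholding keeps top links or top genes deterministically", {
  e <- data.frame(gene_a = c("a", "b", "c"), gene_b = c("b", "c", "d"),
                  weight = c(3, 2, 1))
  net <- new_network(e)
  expect_equal(suppressWarnings(threshold_network(net, "top_links", 5))$edges, net$edges)
  t2 <- threshold_network(net, "top_links", 2)
  expect_setequal(t2$edges$weight, c(3, 2))

  star <- new_network(data.frame(gene_a = "s", gene_b = paste0("n", 1:4),
                                 weight = 4:1))
  tg <- threshold_network(star, "top_genes", 3)
  expect_equal(nrow(tg$edges), 2)
  expect_setequal(tg$edges$weight, c(4, 3))

  expect_warning(threshold_network(net, "top_links", 10), "exceeds")

  # subgraph + monotonicity over a sweep
  big <- simulate_network(30, "erdos_renyi", 100, seed = 3)
  prev <- character(0)
  for (k in c(5, 20, 50, 100)) {
    tk <- threshold_network(big, "top_links", k)
    keys <- paste(tk$edges$gene_a, tk$edges$gene_b)
    expect_true(all(keys %in% paste(big$edges$gene_a, big$edges$gene_b)))
    expect_true(all(prev %in% keys))
    prev <- keys
  }
})
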
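test_that("a noise-free least-squares cell reports perfect accuracy", {
  b <- grn_benchmark(n_networks = 1, n_genes = 20, snr_levels = Inf,
                     methods = "ls", master_seed = 3)
  expect_equal(b$results$aupr, 1.0)
  expect_equal(b$results$status, "ok")
})

test_that("the same master seed reproduces the report byte for byte", {
  run <- function() grn_benchmark(n_networks = 1, n_genes = 15,
                                  snr_levels = c(0.1, 1),
                                  methods = c("ls", "zscore"), master_seed = 11)
  b1 <- run(); b2 <- run()
  drop_secs <- function(b) b$results[, setdiff(names(b$results), "seconds")]
  expect_identical(drop_secs(b1), drop_secs(b2))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_benchmark_report(b1, d1); p2 <- write_benchmark_report(b2, d2)
  expect_identical(readLines(p1["json"]), readLines(p2["json"]))
  # and a different seed gives different numbers
  b3 <- grn_benchmark(n_networks = 1, n_genes = 15, snr_levels = c(0.1, 1),
                      methods = c("ls", "zscore"), master_seed = 12)
  expect_false(identical(b1$results$aupr, b3$results$aupr))
})

test_that("the grid is complete and estimator failures stay isolated", {
  boom <- function(Y, P, ...) stop("estimator exploded")
  b <- grn_benchmark(n_networks = 2, n_genes = 12, snr_levels = 1,
                     methods = list(ls = "ls", boom = boom), master_seed = 5)
  expect_equal(nrow(b$results), 4L)  # 2 networks x 2 methods, all present
  expect_true(all(b$results$status[b$results$method == "ls"] == "ok"))
  expect_true(all(grepl("failed", b$results$status[b$results$method == "boom"])))
  expect_true(all(is.na(b$results$aupr[b$results$method == "boom"])))
})

test_that("the scrambled-design control collapses while intact designs do not", {
  b <- grn_benchmark(n_networks = 2, n_genes = 25, snr_levels = 1,
                     methods = c("ls", "zscore"), master_seed = 21,
                     scramble_control = TRUE)
  res <- b$results
  prev <- sapply(b$golds, function(g) mean(unclass(g) != 0))
  for (i in 1:2) for (m in c("ls", "zscore")) {
    a_int <- res$aupr[res$network == i & res$method == m & res$design == "intact"]
    a_scr <- res$aupr[res$network == i & res$method == m & res$design == "scrambled"]
    expect_gt(a_int, a_scr)
    expect_lt(a_scr, 2 * prev[i])
  }
})

test_that("category separation appears at reduced scale across master seeds", {
  for (seed in c(1, 2, 3)) {
    b <- grn_benchmark(n_networks = 2, n_genes = 30, snr_levels = c(0.1, 1),
                       methods = c("ls", "zscore", "genie3", "clr"),
                       master_seed = seed, n_trees = 50)
    ok <- b$results[b$results$status == "ok", ]
    for (snr in unique(ok$snr)) {
      sub <- ok[ok$snr == snr, ]
      min_p <- min(tapply(sub$aupr[sub$category == "p_based"],
                          sub$method[sub$category == "p_based"], mean))
      max_n <- max(tapply(sub$aupr[sub$category == "non_p_based"],
                          sub$method[sub$category == "non_p_based"], mean))
      expect_gt(min_p, max_n)
    }
  }
})

test_that("similarity analysis matches direct recomputation from stored edge sets", {
  b <- grn_benchmark(n_networks = 2, n_genes = 20, snr_levels = 1,
                     methods = c("ls", "ridge", "clr"), master_seed = 8)
  sim <- similarity_analysis(b)
  J <- sim$levels[[1]]$jaccard
  expect_equal(unname(diag(J)), rep(1, 3))
  direct <- mean(sapply(1:2, function(i)
    jaccard_index(b$edges[[paste(i, 1, "ls", "intact", sep = "|")]],
                  b$edges[[paste(i, 1, "ridge", "intact", sep = "|")]])))
  expect_equal(J["ls", "ridge"], direct)
  # true fraction recomputation
  direct_tf <- mean(sapply(1:2, function(i)
    true_fraction(b$edges[[paste(i, 1, "ls", "intact", sep = "|")]],
                  b$edges[[paste(i, 1, "ridge", "intact", sep = "|")]],
                  which(as.matrix(b$golds[[i]]) != 0))))
  expect_equal(sim$levels[[1]]$true_fraction["ls", "ridge"], direct_tf)
  # single-method and duplicated-method degenerate cases
  b1 <- grn_benchmark(n_networks = 1, n_genes = 15, snr_levels = 1,
                      methods = "ls", master_seed = 8)
  s1 <- similarity_analysis(b1)
  expect_equal(unname(s1$levels[[1]]$jaccard["ls", "ls"]), 1)
  b2 <- grn_benchmark(n_networks = 1, n_genes = 15, snr_levels = 1,
                      methods = list(a = "ls", b = "ls"), master_seed = 8)
  expect_equal(unname(similarity_analysis(b2)$levels[[1]]$jaccard["a", "b"]), 1)
})

test_that("within-category similarity is higher for P-based methods", {
  b <- grn_benchmark(n_networks = 2, n_genes = 30, snr_levels = c(0.1, 1),
                     methods = c("ls", "lasso", "ridge", "genie3", "clr"),
                     master_seed = 31, n_trees = 50)
  s <- similarity_analysis(b)$summary
  for (snr in c(0.1, 1)) {
    jp <- s$mean_jaccard[s$snr == snr & s$category == "p_based"]
    jn <- s$mean_jaccard[s$snr == snr & s$category == "non_p_based"]
    expect_gt(jp, jn)
  }
})
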
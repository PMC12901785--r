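test_that("hypergeometric tails match exact enumeration", {
  expect_equal(hypergeom_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeom_tail(3, 4, 5, 10), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_tail(4, 4, 5, 10), 6 / 252, tolerance = 1e-12)

  # full subset-enumeration oracle over a grid of small universes
  for (N in c(5, 8, 12)) {
    for (n1 in c(0, 2, N %/% 2, N)) {
      for (n2 in c(1, N %/% 3 + 1, N - 1)) {
        for (x in 0:min(n1, n2)) {
          if (n1 + n2 - x > N) next
          expect_equal(hypergeom_tail(x, n1, n2, N),
                       oracle_hyper_tail(x, n1, n2, N), tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(hypergeom_tail(5, 4, 5, 10), "exceeds")
  expect_error(hypergeom_tail(0, 8, 8, 10), "cannot fit")
})

test_that("representation factor matches its definition and edge cases", {
  # x exactly at the chance expectation: RF = 1
  r <- representation_factor(10, 50, 40, 200)
  expect_equal(r$rf, 1.0)
  r0 <- representation_factor(0, 5, 5, 100)
  expect_equal(r0$rf, 0)
  expect_equal(r0$p, 1)
  # background reconstruction round trips
  expect_equal(background_from_rf(r$rf, 10, 50, 40), 200)
  p <- hypergeom_tail(12, 300, 200, 5000)
  expect_equal(background_from_p(p, 12, 300, 200), 5000)
})

test_that("RF of independent random lists averages to about 1", {
  set.seed(51)
  N <- 1000
  rfs <- replicate(1000, {
    l1 <- sample.int(N, 50)
    l2 <- sample.int(N, 50)
    length(intersect(l1, l2)) * N / (50 * 50)
  })
  expect_lt(abs(mean(rfs) - 1), 0.06) # 3 x Monte-Carlo SE
})

test_that("Venn partitions tabulate every disjoint region", {
  v <- venn_partition(list(a = "x", b = "y", c = "z"))
  expect_equal(sum(v), 3)
  expect_equal(unname(v[c("110", "101", "011", "111")]), rep(0L, 4))

  ident <- venn_partition(list(a = letters[1:5], b = letters[1:5],
                               c = letters[1:5]))
  expect_equal(unname(ident["111"]), 5L)
  expect_equal(sum(ident), 5)

  set.seed(52)
  sets <- lapply(1:3, function(i) sample(sprintf("g%04d", 1:400), 100))
  names(sets) <- c("A", "B", "C")
  v3 <- venn_partition(sets)
  expect_equal(sum(v3), length(unique(unlist(sets))))
  # brute-force membership tabulation
  u <- unique(unlist(sets))
  code <- sapply(u, function(g)
    paste(as.integer(c(g %in% sets$A, g %in% sets$B, g %in% sets$C)),
          collapse = ""))
  for (cd in names(v3)) expect_equal(unname(v3[cd]), sum(code == cd))
  expect_error(venn_partition(list(a = "x")), "2 or 3")
})

test_that("GMT files round trip through write and read", {
  coll <- gene_set_collection(list(ALPHA = c("g1", "g2", "g3"),
                                   BETA = c("g2", "g9")), category = "test")
  path <- tempfile(fileext = ".gmt")
  on.exit(unlink(path))
  write_gmt(coll, path, descriptions = c("first", "second"))
  back <- read_gmt(path)
  expect_equal(back$sets, coll$sets)
  expect_error(gene_set_collection(list(c("a"))), "named")
  expect_error(gene_set_collection(list(A = character(0))), "at least one")
})

test_that("over-representation finds a planted set and orders BH q-values", {
  set.seed(53)
  bg <- sprintf("g%05d", 1:10000)
  planted_set <- sample(bg, 100)
  query <- c(sample(planted_set, 50), sample(setdiff(bg, planted_set), 10))
  coll <- gene_set_collection(c(
    list(PLANTED = planted_set),
    setNames(lapply(1:20, function(i) sample(bg, 80)),
             paste0("RND", 1:20))))
  res <- hypergeom_enrichment(query, bg, coll)
  expect_equal(res$set[1], "PLANTED")
  expect_lt(res$q[1], 1e-10)
  # BH q is monotone non-decreasing in p-ranked order
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-15))

  expect_equal(nrow(hypergeom_enrichment(character(0), bg, coll)), 0)
  expect_error(hypergeom_enrichment(c("nope1"), bg, coll), "nope1")
})

test_that("the running-sum enrichment score matches a hand-stepped oracle", {
  scores <- setNames(c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5), paste0("g", 1:10))
  # explicit enumeration of all 10 steps (weight 1)
  run <- numeric(10)
  cur <- 0
  nr <- sum(abs(scores[c("g1", "g3", "g8")]))
  for (i in 1:10) {
    nm <- paste0("g", i)
    cur <- cur + if (nm %in% c("g1", "g3", "g8")) abs(scores[[nm]]) / nr else -1 / 7
    run[i] <- cur
  }
  want <- run[which.max(abs(run))]
  expect_equal(preranked_es(scores, c("g1", "g3", "g8")), want, tolerance = 1e-12)

  # weight 0 reduces to the classical KS statistic on ranks
  run0 <- cumsum(ifelse(paste0("g", 1:10) %in% c("g1", "g3", "g8"), 1 / 3, -1 / 7))
  want0 <- run0[which.max(abs(run0))]
  expect_equal(preranked_es(scores, c("g1", "g3", "g8"), weight = 0), want0,
               tolerance = 1e-12)

  # a top-k set scores higher than the same-size bottom-k set
  es_top <- preranked_es(scores, paste0("g", 1:3))
  es_bot <- preranked_es(scores, paste0("g", 8:10))
  expect_gt(es_top, 0)
  expect_gte(es_top, es_bot)
})

test_that("enrichment scores agree with the independent fgsea implementation", {
  set.seed(54)
  scores <- sort(setNames(rnorm(200), sprintf("g%03d", 1:200)), decreasing = TRUE)
  for (i in 1:5) {
    set <- sample(names(scores), 15)
    got <- preranked_es(scores, set)
    want <- fgsea::calcGseaStat(unname(scores), which(names(scores) %in% set),
                                gseaParam = 1)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("pre-ranked GSEA is seeded, calibrated under the null, and powered", {
  set.seed(55)
  scores <- setNames(rnorm(1000), sprintf("g%04d", 1:1000))
  coll <- gene_set_collection(setNames(
    lapply(1:200, function(i) sample(names(scores), 20)),
    sprintf("NULL%03d", 1:200)))
  r1 <- preranked_gsea(scores, coll, n_perm = 500, seed = 7)
  r2 <- preranked_gsea(scores, coll, n_perm = 500, seed = 7)
  expect_identical(r1, r2)
  # null calibration: ~5% of random sets at p < 0.05 (binomial tolerance)
  frac <- mean(r1$p < 0.05)
  expect_gte(frac, 0.05 - 2.58 * sqrt(0.05 * 0.95 / 200))
  expect_lte(frac, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 200))

  # planted concordant set: all members in the top decile of the ranking
  top <- names(sort(scores, decreasing = TRUE))[1:100]
  coll2 <- gene_set_collection(c(coll$sets[1:50],
                                 list(PLANTED = sample(top, 25))))
  r3 <- preranked_gsea(scores, coll2, n_perm = 500, seed = 8)
  planted <- r3[r3$set == "PLANTED", ]
  expect_gt(planted$nes, 0)
  expect_lt(planted$fdr, 0.05)
})

test_that("gene ranking combines direction and significance deterministically", {
  d <- data.frame(gene = c("b", "a", "c", "d"),
                  log2fc = c(1, 2, -0.5, 1),
                  p = c(0.01, 0.05, 0.001, 0.01))
  r <- rank_genes(d)
  expect_equal(unname(r[["b"]]), 2.0) # p = 0.01, up
  # equal scores tie-break by gene id: b before d
  expect_equal(names(r), c("b", "d", "a", "c"))
  # monotone rescaling of -log10 p preserves the order
  d2 <- d
  d2$p <- 10^(log10(d$p) * 3)
  expect_equal(names(rank_genes(d2)), names(r))
})

test_that("stage-opposition logic equals brute-force set algebra", {
  up_mat <- c("a", "b", "c", "d")
  up_t60 <- c("b", "c", "x")
  down_t90 <- c("c", "b", "y")
  got <- shared_all(list(up_mat, up_t60, down_t90))
  want <- Filter(function(g) g %in% up_mat && g %in% up_t60 && g %in% down_t90,
                 unique(c(up_mat, up_t60, down_t90)))
  expect_setequal(got, want)
  expect_setequal(got, c("b", "c"))
})
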
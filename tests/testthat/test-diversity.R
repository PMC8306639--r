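# Alpha indices, Bray-Curtis, presence/Venn partitions.

test_that("chao1 matches hand-evaluated cases and the vegan estimator", {
  # S=10, F1=4, F2=2 -> 10 + 4*3/(2*3) = 12
  x <- c(rep(5, 4), 1, 1, 1, 1, 2, 2)
  expect_equal(chao1(x), 12)
  # S=10, F1=3, F2=0 -> 10 + 3*2/2 = 13
  y <- c(rep(5, 7), 1, 1, 1)
  expect_equal(chao1(y), 13)
  # no singletons: chao1 == observed richness
  z <- c(4, 5, 6, 2)
  expect_equal(chao1(z), 4)
  expect_error(chao1(c(1.5, 2)), "integer")

  withr::local_seed(4)
  for (i in 1:5) {
    v <- rpois(30, 2)
    v[1] <- v[1] + 1  # ensure non-empty
    expect_equal(chao1(v), unname(vegan::estimateR(v)["S.chao1"]))
  }
})

test_that("chao1 excess over richness equals the bias-corrected term (property)", {
  withr::local_seed(8)
  for (i in 1:20) {
    v <- rpois(40, 1.2)
    if (sum(v) == 0) v[1] <- 1
    f1 <- sum(v == 1); f2 <- sum(v == 2)
    excess <- chao1(v) - sum(v > 0)
    expect_equal(excess, f1 * (f1 - 1) / (2 * (f2 + 1)))
    expect_gte(excess, 0)
  }
})

test_that("Shannon, Simpson and evenness match hand values", {
  expect_equal(shannonIndex(rep(1, 4)), log(4))
  expect_equal(shannonIndex(c(10, 0, 0)), 0)
  expect_equal(shannonIndex(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(round(shannonIndex(c(0.5, 0.25, 0.25)), 6), 1.039721)

  expect_equal(simpsonIndex(c(0.5, 0.25, 0.25)), 0.625)
  expect_equal(simpsonIndex(rep(1, 8)), 1 - 1 / 8)

  expect_equal(evennessIndex(rep(3, 7)), 1)
  expect_equal(round(evennessIndex(c(0.5, 0.25, 0.25)), 4), 0.9428)
  expect_error(shannonIndex(c(0, 0)), "all-zero")
})

test_that("Shannon is permutation- and scale-invariant; evenness is consistent (property)", {
  withr::local_seed(12)
  for (i in 1:10) {
    v <- rgamma(15, 1) * rbinom(15, 1, 0.8)
    if (sum(v) == 0) v[1] <- 1
    expect_equal(shannonIndex(sample(v)), shannonIndex(v))
    expect_equal(shannonIndex(v * 7.3), shannonIndex(v))
    expect_equal(evennessIndex(v),
                 exp(shannonIndex(v)) / sum(v > 0))
  }
})

test_that("alpha summary reproduces means over replicates", {
  tb <- randomCountTable(nOtu = 30, nSample = 6, seed = 21)
  md <- data.frame(grp = rep(c("g1", "g2"), each = 3),
                   row.names = sampleIds(tb))
  alpha <- alphaDiversity(tb)
  smry <- alphaDiversitySummary(tb, md, groupBy = "grp")
  g1 <- smry[smry$condition == "g1" & smry$index == "shannon", ]
  expect_equal(g1$mean, mean(alpha$shannon[1:3]))
  expect_equal(g1$sd, sd(alpha$shannon[1:3]))
  expect_equal(g1$n, 3L)
})

test_that("Bray-Curtis matches hand values, its axioms, and vegan", {
  m <- cbind(s1 = c(1, 1, 0), s2 = c(0, 1, 1), s3 = c(1, 1, 0))
  rownames(m) <- letters[1:3]
  D <- brayCurtis(otuTable(m))
  expect_equal(D["s1", "s2"], 0.5)
  expect_equal(D["s1", "s3"], 0)        # identical columns
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D, t(D))

  disj <- cbind(s1 = c(5, 0), s2 = c(0, 3)); rownames(disj) <- c("a", "b")
  expect_equal(brayCurtis(otuTable(disj))["s1", "s2"], 1)

  one <- cbind(s1 = c(1, 2)); rownames(one) <- c("a", "b")
  expect_error(brayCurtis(otuTable(one)), "two samples")

  tb <- randomCountTable(nOtu = 20, nSample = 7, seed = 31)
  expect_equal(brayCurtis(tb),
               as.matrix(vegan::vegdist(t(abundances(tb)), "bray")),
               tolerance = 1e-12)
})

test_that("vennPartition performs exact set algebra", {
  vp <- vennPartition(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
  expect_equal(unname(vp$sizes[c("A&B", "A", "B")]), c(2L, 1L, 1L))
  expect_setequal(vp$regions[["A&B"]], c("2", "3"))

  same <- vennPartition(list(A = letters[1:4], B = letters[1:4]))
  expect_equal(unname(same$sizes["A&B"]), 4L)
  expect_equal(unname(same$sizes["A"]), 0L)

  expect_error(vennPartition(list(A = 1, B = 2, C = 3, D = 4)),
               "2 or 3 groups")
})

test_that("vennPartition agrees with a brute-force membership loop (property)", {
  withr::local_seed(9)
  universe <- sprintf("o%03d", 1:60)
  for (i in 1:10) {
    sets <- list(A = sample(universe, 25), B = sample(universe, 20),
                 C = sample(universe, 30))
    vp <- vennPartition(sets)
    # regions are disjoint and cover the union
    allIds <- unlist(vp$regions)
    expect_false(anyDuplicated(allIds) > 0)
    expect_setequal(allIds, unique(unlist(sets)))
    # brute force: classify every OTU by its membership pattern
    for (id in unique(unlist(sets))) {
      pat <- names(sets)[vapply(sets, function(s) id %in% s, logical(1))]
      expect_true(id %in% vp$regions[[paste(pat, collapse = "&")]])
    }
  }
})

test_that("presenceSets supports any- and all-replicate detection", {
  m <- cbind(a1 = c(1, 0, 2), a2 = c(3, 0, 0), b1 = c(0, 1, 1),
             b2 = c(0, 2, 1))
  rownames(m) <- c("x", "y", "z")
  md <- data.frame(grp = c("A", "A", "B", "B"), row.names = colnames(m))
  anySets <- presenceSets(otuTable(m), md, "grp", mode = "any")
  allSets <- presenceSets(otuTable(m), md, "grp", mode = "all")
  expect_setequal(anySets$A, c("x", "z"))
  expect_setequal(allSets$A, "x")
  expect_setequal(allSets$B, c("y", "z"))
})
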
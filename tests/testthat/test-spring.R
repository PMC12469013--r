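test_that("composite value normalizes and orients the channels correctly", {
  snb <- c(a = -10, b = -4, c = 0)
  fld <- c(a = 0.5, b = 1, c = 2)
  L <- composite_value(snb, fld)
  # node 'a' attains max |SNB| and min dimension -> both channels 1 -> L = 1
  expect_equal(unname(L["a"]), 1)
  expect_true(all(L >= 0 & L <= 1))

  # lambda = 1: ranking equals ranking by oriented SNB
  L1 <- composite_value(snb, fld, lambda = 1)
  expect_equal(rank_nodes(L1), rank_nodes(abs(snb)))

  # signed mode preserves the literal formula: most negative SNB -> channel 0
  Ls <- composite_value(snb, fld, lambda = 1, orientation = "signed")
  expect_equal(unname(Ls["a"]), 0)
  expect_equal(unname(Ls["c"]), 1)

  # dimension mode feeds the raw exponent; locality mode is its mirror
  Ld <- composite_value(snb, fld, lambda = 0, fld_orientation = "dimension")
  expect_equal(unname(Ld), unname((fld - 0.5) / 1.5))
  Ll <- composite_value(snb, fld, lambda = 0, fld_orientation = "locality")
  expect_equal(unname(Ll), unname(1 - (fld - 0.5) / 1.5))

  # constant SNB: channel contributes 0 to every node (either orientation)
  Lc <- composite_value(c(a = -3, b = -3, c = -3), fld, lambda = 0.5,
                        fld_orientation = "dimension")
  expect_equal(unname(Lc), unname(0.5 * (fld - 0.5) / 1.5))
  # constant FLD stays zero, never flips to one under the locality complement
  Lf <- composite_value(snb, c(a = 1, b = 1, c = 1), lambda = 0.5)
  expect_equal(unname(Lf), unname(0.5 * minmax_oracle(abs(snb))))

  expect_error(composite_value(snb, fld, lambda = 1.2), "lambda")
})

test_that("full spring model matches the pairwise summation oracle", {
  # K3 with all L = 1: d = 1, all d_ij = 1 -> zero deformation everywhere
  k3 <- fixture_graph("complete", n = 3)
  dm3 <- all_pairs_distances(k3)
  L1 <- c("1" = 1, "2" = 1, "3" = 1)
  expect_equal(unname(ism_full(dm3, L1)), c(0, 0, 0))

  # path 1-2-3, L = 1: ISM = (1, 2, 1)
  p3 <- fixture_graph("path", n = 3)
  dmp <- all_pairs_distances(p3)
  expect_equal(unname(ism_full(dmp, L1)), c(1, 2, 1))

  # a zero-L node contributes nothing anywhere
  L0 <- c("1" = 0, "2" = 1, "3" = 1)
  ism0 <- ism_full(dmp, L0)
  expect_equal(unname(ism0["1"]), 0)
  expect_equal(unname(ism0["2"]), 1)   # only the 2-3 pair remains

  # brute-force double loop on a random graph
  g <- random_connected_graph(11)
  dm <- all_pairs_distances(g)
  set.seed(1); L <- stats::setNames(stats::runif(nrow(dm)), rownames(dm))
  d <- max(dm)
  brute <- vapply(rownames(dm), function(i) {
    sum(vapply(setdiff(rownames(dm), i),
               function(j) L[[i]] * L[[j]] * (d - dm[i, j]), numeric(1)))
  }, numeric(1))
  expect_scores_equal(ism_full(dm, L), brute)
})

test_that("influence range follows the force-balance formula with clamping", {
  # symmetric case: L_i = L_l, d_l = 4 -> R = 2
  p5 <- fixture_graph("path", n = 5)
  dm <- all_pairs_distances(p5)
  Leq <- stats::setNames(rep(0.7, 5), rownames(dm))
  R <- influence_range(dm, Leq)
  expect_equal(unname(R["1"]), 2)   # farthest node at distance 4
  expect_equal(unname(R["3"]), 1)   # d_l = 2 -> R = 1 (clamp floor)

  # dominant node reaches everywhere: L_i >> L_l with d_l = d
  Ldom <- stats::setNames(c(1, 1e-9, 1e-9, 1e-9, 1e-9), rownames(dm))
  expect_equal(unname(influence_range(dm, Ldom)["1"]), 4, tolerance = 1e-6)

  # hand substitution on a fixed toy assignment
  Ltoy <- stats::setNames(c(0.9, 0.1, 0.5, 0.3, 0.2), rownames(dm))
  d <- 4
  # node 2: farthest is node 5 (d_l = 3); ((L2 - L5) d + L5 * 3)/(L5 + L2)
  expect_equal(unname(influence_range(dm, Ltoy)["2"]),
               min(max(((0.1 - 0.2) * d + 0.2 * 3) / (0.2 + 0.1), 1), d))
  # farthest-node tie for node 3 ({1, 5} at distance 2): smaller label 1 wins
  expect_equal(unname(influence_range(dm, Ltoy)["3"]),
               min(max(((0.5 - 0.9) * d + 0.9 * 2) / (0.9 + 0.5), 1), d))

  expect_warning(Rz <- influence_range(dm, Leq * 0), "zero composite")
  expect_equal(unname(Rz), rep(1, 5))
})

test_that("range-restricted spring model equals the masked brute force", {
  g <- random_connected_graph(23)
  dm <- all_pairs_distances(g)
  set.seed(2); L <- stats::setNames(stats::runif(nrow(dm)), rownames(dm))
  R <- influence_range(dm, L)
  d <- max(dm)
  brute <- vapply(rownames(dm), function(i) {
    js <- setdiff(rownames(dm), i)
    js <- js[dm[i, js] <= R[[i]]]
    sum(vapply(js, function(j) L[[i]] * L[[j]] * (d - dm[i, j]), numeric(1)))
  }, numeric(1))
  expect_scores_equal(ism_ranged(dm, L, R), brute)

  # R_i >= d for all i -> identical to the full model
  Rfull <- stats::setNames(rep(d, nrow(dm)), rownames(dm))
  expect_equal(ism_ranged(dm, L, Rfull), ism_full(dm, L), tolerance = 1e-9)

  # R_i = 1 -> only direct neighbors contribute
  Rone <- stats::setNames(rep(1, nrow(dm)), rownames(dm))
  A <- adj_matrix(g)
  brute1 <- stats::setNames((d - 1) * L * as.numeric(A[rownames(dm), rownames(dm)] %*% L),
                            rownames(dm))
  expect_scores_equal(ism_ranged(dm, L, Rone), brute1)
})

test_that("greedy attenuation ranking follows the update contract", {
  # ISM(v_i) = 1, neighbor sum 3 -> factor 0.75; neighbor at 2 drops to 1.5
  star3 <- fixture_graph("star", k = 3)
  ism <- c("1" = 2, "2" = 1, "3" = 1, "4" = 1)
  rk <- snefld_rank(star3, ism)
  expect_equal(rk$node[1], "1")
  # factor = 1 - 2/(2+3) = 0.6; each leaf 1 -> 0.6
  expect_equal(rk$score, c(2, 0.6, 0.6, 0.6))
  expect_equal(rk$node, c("1", "2", "3", "4"))   # ties to smaller label

  # zero-value node suppresses nothing
  p3 <- fixture_graph("path", n = 3)
  rk0 <- snefld_rank(p3, c("1" = 0, "2" = 0, "3" = 0))
  expect_equal(rk0$score, c(0, 0, 0))
  expect_equal(rk0$node, c("1", "2", "3"))

  # output is a permutation with non-increasing scores when all ISM > 0
  g <- random_connected_graph(31)
  set.seed(3)
  ismr <- stats::setNames(stats::runif(igraph::gorder(g), 0.1, 2),
                          igraph::V(g)$name)
  rkg <- snefld_rank(g, ismr)
  expect_setequal(rkg$node, igraph::V(g)$name)
  expect_true(all(diff(rkg$score) <= 1e-12))
  expect_true(all(rkg$score >= 0))
})

test_that("attenuation factor stays in (0, 1] and equals 1 iff ISM = 0", {
  for (ismv in c(0, 0.5, 1, 7)) {
    nbsum <- 3
    f <- if (ismv == 0) 1 else 1 - ismv / (ismv + nbsum)
    expect_gt(f, 0)
    expect_lte(f, 1)
    expect_identical(f == 1, ismv == 0)
  }
})

test_that("end-to-end ranking is deterministic and tie-stable under relabeling", {
  g <- fixture_graph("two_blobs", a = 5, b = 5)
  r1 <- snefld_sm(g)
  r2 <- snefld_sm(g)
  expect_identical(r1, r2)

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  utils::write.table(r1, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(r2, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical output

  # the planted bridge dominates betweenness, hence the SNB channel
  bc <- betweenness_centrality(g)
  expect_equal(names(which.max(bc)), "bridge")
})
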
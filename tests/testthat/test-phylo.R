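test_that("force_ultrametric extends terminal edges to the max depth", {
  tree <- ape::read.tree(text = "((A:1,B:2):1,C:3);")
  out <- force_ultrametric(tree)
  d <- setNames(tip_depths(out), out$tip.label)
  expect_equal(unname(d[c("A", "B", "C")]), c(3, 3, 3))
  # topology and internal edges untouched; A's terminal edge gets the slack
  expect_equal(ape::write.tree(ape::di2multi(out, tol = 0)),
               "((A:2,B:2):1,C:3);")
  # idempotent on an already-ultrametric tree
  again <- force_ultrametric(out)
  expect_equal(again$edge.length, out$edge.length, tolerance = 1e-12)
})

test_that("force_ultrametric works on random trees (property)", {
  for (s in 1:5) {
    set.seed(s)
    tree <- ape::rtree(20)
    out <- force_ultrametric(tree)
    d <- tip_depths(out)
    expect_lt(diff(range(d)) / max(d), 1e-9)
    expect_identical(out$edge[, ], tree$edge[, ])
  }
})

test_that("cophenetic distances match a brute-force path-sum oracle", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(cophenetic_matrix(cherry)["A", "B"], 2)
  star <- ape::read.tree(text = "(A:3,B:3,C:3,D:3);")
  dm <- cophenetic_matrix(star)
  expect_true(all(dm[upper.tri(dm)] == 6))
  for (s in 1:3) {
    set.seed(s)
    tree <- ape::rtree(12)
    dm <- cophenetic_matrix(tree)
    oracle <- brute_force_cophenetic(tree)
    expect_equal(dm[rownames(oracle), colnames(oracle)], oracle,
                 tolerance = 1e-10)
  }
})

test_that("grafting relabels singletons and builds cherries at depth", {
  genus_tree <- force_ultrametric(ape::read.tree(
    text = "((GenA:2,GenB:2):1,GenC:3);"))
  sbg <- list(GenA = "GenA one", GenB = c("GenB one", "GenB two"))
  out <- graft_species(genus_tree, sbg, seed = 1)
  expect_true(all(c("GenA one", "GenB one", "GenB two", "GenC") %in%
                    out$tip.label))
  d <- setNames(tip_depths(out), out$tip.label)
  expect_equal(unname(d), rep(3, 4), tolerance = 1e-9)
  # genus with zero species keeps its tip; unknown genus warns and drops
  expect_warning(graft_species(genus_tree, list(GenZ = "GenZ sp"), seed = 1),
                 "not in tree")
})

test_that("grafting preserves ultrametricity and the genus backbone", {
  dat <- sim_fixture()
  gt <- force_ultrametric(dat$tree)
  sbg <- unique(data.frame(species = dat$specimens$species,
                           genus = dat$specimens$genus))
  out <- graft_species(gt, sbg, seed = 5)
  expect_lt(diff(range(tip_depths(out))) / max(tip_depths(out)), 1e-9)
  expect_identical(graft_species(gt, sbg, seed = 5)$tip.label, out$tip.label)

  # cross-genus species distance differs from the genus-level distance by at
  # most the two terminal edge lengths (the grafting offsets)
  gd <- cophenetic_matrix(gt)
  sp_d <- cophenetic_matrix(out)
  term_len <- setNames(gt$edge.length[match(seq_along(gt$tip.label),
                                            gt$edge[, 2])], gt$tip.label)
  genera <- unique(sbg$genus)[1:4]
  for (i in 1:3) for (j in (i + 1):4) {
    gi <- genera[i]; gj <- genera[j]
    si <- sbg$species[sbg$genus == gi][1]
    sj <- sbg$species[sbg$genus == gj][1]
    expect_lte(abs(sp_d[si, sj] - gd[gi, gj]),
               2 * (term_len[gi] + term_len[gj]) + 1e-9)
  }
})

test_that("mpd: pairs, star subsets, and a 6-pair enumeration oracle", {
  tree <- ape::read.tree(text = "((A:1,B:1):2,(C:2,D:2):1);")
  dm <- cophenetic_matrix(tree)
  expect_equal(mpd(c("A", "B"), dm), 2)
  expect_true(is.na(mpd("A", dm)))
  star <- cophenetic_matrix(ape::read.tree(text = "(A:4,B:4,C:4,D:4);"))
  expect_equal(mpd(c("A", "C", "D"), star), 8)
  # 4 species: mean over the 6 unordered pairs, enumerated by hand
  pairs <- combn(c("A", "B", "C", "D"), 2)
  oracle <- mean(apply(pairs, 2, function(p) dm[p[1], p[2]]))
  expect_equal(mpd(c("A", "B", "C", "D"), dm), oracle)
  # logical-community interface
  expect_equal(mpd(rownames(dm) %in% c("A", "B"), dm), 2)
})

test_that("ses_mpd: degenerate null, forced sign, determinism", {
  set.seed(31)
  tree <- force_ultrametric(ape::rtree(10))
  dm <- cophenetic_matrix(tree)
  pool <- rownames(dm)

  whole <- ses_mpd(pool, dm, pool = pool, n_null = 100, seed = 1)
  expect_true(whole$degenerate)
  expect_equal(whole$mpd_obs, whole$null_mean)
  expect_equal(whole$ses, 0)

  # the two most distant tips must look phylogenetically even (ses > 0):
  # verified by enumerating all 45 pairs of the pool
  idx <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  far <- rownames(dm)[idx]
  all_pairs <- combn(pool, 2)
  pair_mpds <- apply(all_pairs, 2, function(p) dm[p[1], p[2]])
  expect_equal(max(pair_mpds), dm[far[1], far[2]])
  s <- ses_mpd(far, dm, pool = pool, n_null = 999, seed = 2)
  expect_gt(s$ses, 0)

  s2 <- ses_mpd(far, dm, pool = pool, n_null = 999, seed = 2)
  expect_identical(s$ses, s2$ses)
})

test_that("SES is invariant to branch-length rescaling", {
  set.seed(8)
  tree <- force_ultrametric(ape::rtree(15))
  dm <- cophenetic_matrix(tree)
  comm <- rownames(dm)[1:6]
  a <- ses_mpd(comm, dm, n_null = 499, seed = 3)
  b <- ses_mpd(comm, dm * 7.5, n_null = 499, seed = 3)
  expect_equal(a$ses, b$ses, tolerance = 1e-10)
})

test_that("ses_mpd_units scores every unit against a common pool", {
  dat <- sim_fixture()
  gt <- force_ultrametric(dat$tree)
  sbg <- unique(data.frame(species = dat$specimens$species,
                           genus = dat$specimens$genus))
  dm <- cophenetic_matrix(graft_species(gt, sbg, seed = 2))
  ycm <- build_year_matrix(dat$specimens, dat$grouping)
  tab <- ses_mpd_units(ycm, dm, n_null = 199, seed = 4)
  expect_equal(nrow(tab), nrow(ycm$units))
  rich <- rowSums(ycm$counts > 0)
  expect_true(all(is.finite(tab$ses[rich >= 2])))
  expect_true(all(tab$ses >= -6 & tab$ses <= 6, na.rm = TRUE))
})
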
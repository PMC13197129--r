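test_that("pair sampling is uniform over distinct unordered pairs and seeded", {
  sp <- rnafrag:::.sample_pairs
  for (n in c(3L, 7L, 20L)) {
    all_pairs <- sp(n, Inf, 1)
    expect_identical(nrow(all_pairs), as.integer(n * (n - 1) / 2))
    expect_true(all(all_pairs[, 1] < all_pairs[, 2]))
    expect_true(all(all_pairs <= n & all_pairs >= 1))
    expect_identical(anyDuplicated(paste(all_pairs[, 1], all_pairs[, 2])), 0L)
    ref <- t(utils::combn(n, 2))
    expect_identical(sort(paste(all_pairs[, 1], all_pairs[, 2])),
                     sort(paste(ref[, 1], ref[, 2])))
  }
  s1 <- sp(50, 100, 7); s2 <- sp(50, 100, 7); s3 <- sp(50, 100, 8)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
})

test_that("RMSD correlation is exactly 1 against itself and seeded-reproducible", {
  frags <- make_conformer_set(8, seed = 51)
  self <- rmsd_correlation(frags, "M2S0B1", "M2S0B1", n_pairs = 20, seed = 3)
  expect_identical(self$pcc, 1)
  r1 <- rmsd_correlation(frags, "FULL15", "M6S0B0", n_pairs = 15, seed = 5)
  r2 <- rmsd_correlation(frags, "FULL15", "M6S0B0", n_pairs = 15, seed = 5)
  expect_identical(r1$pairs, r2$pairs)
  expect_identical(r1$pcc, r2$pcc)
  expect_error(rmsd_correlation(frags[1, ], "FULL15", "M6S0B0"), "at least 2")
})

test_that("the sampled PCC matches a closed-form covariance oracle", {
  frags <- make_conformer_set(10, seed = 52)
  r <- rmsd_correlation(frags, "FULL15", "M0S0B3", n_pairs = Inf, seed = 1)
  expect_equal(r$pcc, oracle_pcc(r$pairs$rmsd_a, r$pairs$rmsd_b),
               tolerance = 1e-12)
  # and the rmsd columns themselves match direct recomputation
  ca <- fragment_coords(frags, "FULL15"); cb <- fragment_coords(frags, "M0S0B3")
  for (row in sample(nrow(r$pairs), 10)) {
    i <- r$pairs$i[[row]]; j <- r$pairs$j[[row]]
    expect_equal(r$pairs$rmsd_a[[row]], kabsch_rmsd(ca[[i]], ca[[j]]),
                 tolerance = 1e-12)
    expect_equal(r$pairs$rmsd_b[[row]], kabsch_rmsd(cb[[i]], cb[[j]]),
                 tolerance = 1e-12)
  }
})

test_that("zero-variance RMSD sets report an undefined PCC, never zero", {
  base <- make_fragment("GAC")
  copies <- dplyr::bind_rows(purrr::map(1:4, function(i) {
    cp <- rigid_copy(base, translation = rnorm(3))
    cp$entry_id <- sprintf("SYN%04d", i)
    cp
  }))
  r <- rmsd_correlation(copies, "FULL15", "M6S0B0", n_pairs = Inf, seed = 1)
  expect_true(is.na(r$pcc))
})

test_that("pseudo-torsion grid coverage counts 5-degree cells correctly", {
  empty <- grid_coverage(tibble::tibble(eta = numeric(), theta = numeric()))
  expect_identical(empty$total_bins, 5184L)
  expect_identical(empty$covered_bins, 0L)
  # exhaustive sweep: one point per cell covers everything
  centers <- seq(-177.5, 177.5, by = 5)
  sweep_tbl <- tidyr::expand_grid(eta = centers, theta = centers)
  full <- grid_coverage(sweep_tbl)
  expect_identical(full$covered_bins, full$total_bins)
  expect_identical(full$fraction, 1)
  # +180 maps into the last cell, not a phantom one
  edge <- grid_coverage(tibble::tibble(eta = c(180, 177), theta = c(180, 179)))
  expect_identical(edge$covered_bins, 1L)
  # coverage is monotone under appending points
  some <- sweep_tbl[1:100, ]
  more <- dplyr::bind_rows(some, sweep_tbl[101:150, ])
  expect_gte(grid_coverage(more)$covered_bins,
             grid_coverage(some)$covered_bins)
  expect_error(grid_coverage(sweep_tbl, bin_width = 7), "divisor")
  expect_identical(grid_coverage(sweep_tbl, bin_width = 10)$total_bins, 1296L)
})

test_that("angle distance vs RMSD separates torsion-blind conformer changes", {
  # identical P/C4' backbones, glycosidic chi rotated and sugar repuckered:
  # eta/theta unchanged, full-atom RMSD large -- the discordant case the
  # pseudo-torsion metric cannot see
  a <- make_fragment("GAC", entry_id = "SYN0001")
  flipped <- aform_torsions(); flipped["chi"] <- 60
  b <- make_fragment("GAC", flipped, entry_id = "SYN0002",
                     pucker = "C2'-endo")
  tor <- pseudo_torsions(dplyr::bind_rows(a, b), position = 2)
  expect_lt(angle_distance(tor$eta[1], tor$theta[1], tor$eta[2], tor$theta[2]),
            1e-6)
  res <- angle_distance_vs_rmsd(dplyr::bind_rows(a, b), n_pairs = Inf, seed = 1)
  expect_identical(nrow(res$pairs), 1L)
  expect_lt(res$pairs$angle_dist, 10)
  expect_gt(res$pairs$rmsd, 1)
  expect_identical(res$fraction_discordant, 1)
})

test_that("angle-distance statistics match brute-force enumeration", {
  frags <- make_conformer_set(12, seed = 53)
  res <- angle_distance_vs_rmsd(frags, n_pairs = Inf, seed = 1)
  tor <- pseudo_torsions(frags, position = 2)
  coords <- fragment_coords(frags, "FULL15")
  n <- nrow(frags)
  ad <- c(); rd <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ad <- c(ad, angle_distance(tor$eta[i], tor$theta[i], tor$eta[j], tor$theta[j]))
    rd <- c(rd, kabsch_rmsd(coords[[i]], coords[[j]]))
  }
  expect_equal(res$pcc, oracle_pcc(ad, rd), tolerance = 1e-12)
  expect_equal(res$fraction_discordant,
               if (any(ad < 10)) mean(rd[ad < 10] > 1) else NA_real_)
  expect_error(angle_distance_vs_rmsd(make_fragment("GACU")), "tri-nucleotide")
})

test_that("rigid copies give zero discordant fraction and undefined PCC", {
  base <- make_fragment("GAC")
  copies <- dplyr::bind_rows(purrr::map(1:4, function(i) {
    cp <- rigid_copy(base); cp$entry_id <- sprintf("SYN%04d", i); cp
  }))
  res <- angle_distance_vs_rmsd(copies, n_pairs = Inf, seed = 1)
  expect_true(is.na(res$pcc))
  expect_identical(res$fraction_discordant, 0)
})

test_that("region classification is exhaustive over pairing patterns", {
  for (k in 2:5) {
    frag <- make_fragment(strrep("G", k), entry_id = "E1")
    patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    for (p in seq_len(nrow(patterns))) {
      paired_at <- which(unlist(patterns[p, ]))
      bp <- if (length(paired_at) == 0)
        tibble::tibble(entry_id = character(), chain1 = character(),
                       seq1 = integer(), chain2 = character(), seq2 = integer())
      else
        tibble::tibble(entry_id = "E1", chain1 = "A", seq1 = paired_at,
                       chain2 = "B", seq2 = 100L + paired_at)
      lab <- classify_regions(frag, bp)$region
      want <- if (length(paired_at) == k) "helix"
        else if (length(paired_at) == 0) "loop" else "mixed_HL"
      expect_identical(as.character(lab), want)
    }
  }
})

test_that("region labels ignore pair order, duplicates and self-pairs", {
  frag <- make_fragment("GAC", entry_id = "E1")
  bp <- tibble::tibble(entry_id = "E1",
                       chain1 = c("B", "A", "A"),
                       seq1 = c(101L, 2L, 3L),
                       chain2 = c("A", "B", "A"),
                       seq2 = c(1L, 102L, 3L))  # last row is a self-pair
  out <- classify_regions(frag, bp)
  expect_identical(as.character(out$region), "mixed_HL")
  expect_identical(out$n_paired, 2L)
  out2 <- classify_regions(frag, bp[sample(nrow(bp)), ])
  expect_identical(out$region, out2$region)
})

test_that("sequence tallies count representatives and conserve totals", {
  frags <- dplyr::bind_rows(
    make_fragment("GAA", entry_id = "SYN0001"),
    make_fragment("GAA", entry_id = "SYN0002"),
    make_fragment("UUU", entry_id = "SYN0003"))
  counts <- sequence_counts(frags)
  expect_identical(counts$sequence, c("GAA", "UUU"))
  expect_identical(counts$n, c(2L, 1L))
  expect_identical(sum(counts$n), nrow(frags))
  set.seed(54)
  many <- dplyr::bind_rows(purrr::map(1:10, function(i)
    make_fragment(paste(sample(c("A", "C", "G", "U"), 3, TRUE), collapse = ""),
                  entry_id = sprintf("SYN%04d", i))))
  expect_identical(sum(sequence_counts(many)$n), 10L)
})

test_that("autoplot methods return ggplot objects", {
  corp <- make_yearly_corpus(data.frame(year = 2001:2002, n_novel = c(2, 1)),
                             dir = withr::local_tempdir(), seed = 55)
  gs <- build_yearly_library(corp$fragments, "FULL15")
  expect_s3_class(autoplot(gs), "ggplot")
  r <- rmsd_correlation(corp$fragments, "FULL15", "M6S0B0",
                        n_pairs = Inf, seed = 1)
  expect_s3_class(autoplot(r), "ggplot")
  tor <- pseudo_torsions(corp$fragments)
  expect_s3_class(plot_pseudo_torsion_grid(tor), "ggplot")
})
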
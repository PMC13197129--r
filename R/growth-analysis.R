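# Pearson correlation, or NA when either side is (numerically) constant:
# a degenerate PCC is reported as missing, never silently zero
.pcc_or_na <- function(a, b, tol = 1e-9) {
  if (length(a) < 2L) return(NA_real_)
  if (stats::sd(a) < tol || stats::sd(b) < tol) return(NA_real_)
  stats::cor(a, b)
}

# uniform sample of n_pairs distinct unordered index pairs from 1..n,
# reproducible under `seed`; returns a two-column integer matrix (i < j)
.sample_pairs <- function(n, n_pairs, seed) {
  if (n < 2L) stop("need at least 2 fragments to form pairs")
  total <- n * (n - 1) / 2
  idx <- if (n_pairs >= total) seq_len(total) else
    withr::with_seed(seed, sort(sample.int(total, n_pairs)))
  # invert the row-major upper-triangle linear index
  i <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * idx))
  offset <- idx - (i - 1) * n + i * (i - 1) / 2
  cbind(i = as.integer(i), j = as.integer(i + offset))
}

#' Correlation between RMSDs under two representations
#'
#' Samples unordered fragment pairs uniformly (without replacement, fixed
#' seed, all pairs when fewer exist than requested), computes the Kabsch
#' RMSD of every sampled pair under both frames, and reports the Pearson
#' correlation coefficient between the two RMSD sets. Used to judge how
#' faithfully a reduced frame reproduces full-atom structural distances.
#'
#' @param fragments Fragment tibble (>= 2 rows, equal lengths).
#' @param frame_a,frame_b The two representations.
#' @param n_pairs Number of pairs to sample.
#' @param seed Integer RNG seed for pair sampling.
#' @return An object of class `rmsd_correlation`: list with `pcc` (`NA`
#'   when either RMSD set has zero variance), `pairs` (tibble: i, j,
#'   rmsd_a, rmsd_b), `frame_a`, `frame_b`, `n_pairs`.
#' @export
rmsd_correlation <- function(fragments, frame_a, frame_b,
                             n_pairs = 1e5, seed = 1) {
  if (nrow(fragments) < 2L) stop("need at least 2 fragments")
  if (dplyr::n_distinct(fragments$k) > 1L) stop("fragments of mixed lengths")
  fa <- frame_spec(frame_a); fb <- frame_spec(frame_b)
  pairs <- .sample_pairs(nrow(fragments), n_pairs, seed)
  ca <- fragment_coords(fragments, fa)
  cb <- if (identical(fa$name, fb$name)) ca else fragment_coords(fragments, fb)
  ra <- vapply(seq_len(nrow(pairs)), function(r)
    kabsch_rmsd(ca[[pairs[r, 1]]], ca[[pairs[r, 2]]]), numeric(1))
  rb <- if (identical(fa$name, fb$name)) ra else
    vapply(seq_len(nrow(pairs)), function(r)
      kabsch_rmsd(cb[[pairs[r, 1]]], cb[[pairs[r, 2]]]), numeric(1))
  pcc <- if (identical(fa$name, fb$name)) 1 else .pcc_or_na(ra, rb)
  structure(
    list(pcc = pcc,
         pairs = tibble::tibble(i = pairs[, 1], j = pairs[, 2],
                                rmsd_a = ra, rmsd_b = rb),
         frame_a = fa$name, frame_b = fb$name, n_pairs = nrow(pairs)),
    class = "rmsd_correlation")
}

#' @export
print.rmsd_correlation <- function(x, ...) {
  cat("<rmsd_correlation>", x$frame_a, "vs", x$frame_b, "| PCC =",
      format(x$pcc, digits = 4), "over", x$n_pairs, "pair(s)\n")
  invisible(x)
}

#' @export
tidy.rmsd_correlation <- function(x, ...) x$pairs

#' @export
glance.rmsd_correlation <- function(x, ...) {
  tibble::tibble(frame_a = x$frame_a, frame_b = x$frame_b,
                 pcc = x$pcc, n_pairs = x$n_pairs)
}

#' Pseudo-torsion grid coverage
#'
#' Bins (eta, theta) pairs on a square grid of `bin_width`-degree cells
#' over (-180, 180\]^2 (half-open cells, +180 mapped into the last cell)
#' and counts the cells hit at least once. With the default 5-degree bins
#' the grid has 5184 cells.
#'
#' @param torsions Tibble (or data frame) with `eta` and `theta` columns
#'   in degrees, e.g. from [pseudo_torsions()].
#' @param bin_width Cell width in degrees; must divide 360.
#' @return A one-row tibble: `covered_bins`, `total_bins`, `fraction`.
#' @export
grid_coverage <- function(torsions, bin_width = 5) {
  if (bin_width <= 0 || (360 %% bin_width) != 0)
    stop("bin_width must be a positive divisor of 360")
  nb <- as.integer(360 / bin_width)
  bin_of <- function(x) pmin(floor((x + 180) / bin_width), nb - 1L)
  covered <- if (nrow(torsions) == 0L) 0L else
    dplyr::n_distinct(paste(bin_of(torsions$eta), bin_of(torsions$theta)))
  tibble::tibble(covered_bins = as.integer(covered),
                 total_bins = nb * nb,
                 fraction = covered / (nb * nb))
}

#' Angle distance versus full-atom RMSD
#'
#' For sampled pairs of tri-nucleotide fragments, compares the
#' pseudo-torsion angle distance (evaluated at the central nucleotide)
#' with the superposition RMSD under `frame`. Reports the Pearson
#' correlation between the two, and the fraction of torsionally similar
#' pairs (angle distance below `angle_cutoff`) that are nonetheless
#' structurally distinct (RMSD above `rmsd_cutoff`) — the failure mode of
#' describing RNA backbone conformation by eta/theta alone.
#'
#' @param fragments Tri-nucleotide fragment tibble.
#' @param n_pairs,seed Pair sampling as in [rmsd_correlation()].
#' @param frame Representation for the RMSD (default the 15 common heavy
#'   atoms).
#' @param angle_cutoff Angle-distance threshold, degrees.
#' @param rmsd_cutoff RMSD threshold, Angstrom.
#' @return A list with `pcc` (`NA` if degenerate), `fraction_discordant`
#'   (`NA` when no pair passes the angle cutoff), and `pairs` (tibble: i,
#'   j, angle_dist, rmsd).
#' @export
angle_distance_vs_rmsd <- function(fragments, n_pairs = 1e5, seed = 1,
                                   frame = "FULL15", angle_cutoff = 10,
                                   rmsd_cutoff = 1) {
  if (any(fragments$k != 3L))
    stop("angle-distance analysis is defined for tri-nucleotides")
  tor <- pseudo_torsions(fragments, position = 2L)
  pairs <- .sample_pairs(nrow(fragments), n_pairs, seed)
  coords <- fragment_coords(fragments, frame)
  ad <- angle_distance(tor$eta[pairs[, 1]], tor$theta[pairs[, 1]],
                       tor$eta[pairs[, 2]], tor$theta[pairs[, 2]])
  rd <- vapply(seq_len(nrow(pairs)), function(r)
    kabsch_rmsd(coords[[pairs[r, 1]]], coords[[pairs[r, 2]]]), numeric(1))
  pcc <- .pcc_or_na(ad, rd)
  close_ang <- ad < angle_cutoff
  fraction <- if (!any(close_ang)) NA_real_ else
    mean(rd[close_ang] > rmsd_cutoff)
  list(pcc = pcc, fraction_discordant = fraction,
       pairs = tibble::tibble(i = pairs[, 1], j = pairs[, 2],
                              angle_dist = ad, rmsd = rd))
}

#' Read a base-pair annotation table
#'
#' Tab-separated with a header and columns `entry_id`, `chain1`, `seq1`,
#' `chain2`, `seq2` — one row per (unordered) base pair, as produced by an
#' external annotation tool such as DSSR.
#'
#' @param path TSV file.
#' @return A tibble of base pairs.
#' @export
read_base_pairs <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("entry_id", "chain1", "seq1", "chain2", "seq2")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("base-pair table lacks column(s): ", paste(missing, collapse = ", "))
  tibble::as_tibble(df[need])
}

#' Classify fragments into helix, loop and mixed helix-loop regions
#'
#' A fragment is `helix` when all of its nucleotides are base-paired,
#' `loop` when none are, and `mixed_HL` otherwise. Pairing status comes
#' from an external base-pair annotation (see [read_base_pairs()]);
#' self-pairs are ignored and pair order is irrelevant.
#'
#' @param fragments Fragment tibble.
#' @param base_pairs Base-pair tibble (`entry_id`, `chain1`, `seq1`,
#'   `chain2`, `seq2`).
#' @return `fragments` with an added `region` factor column
#'   (helix / loop / mixed_HL) and `n_paired` integer column.
#' @export
classify_regions <- function(fragments, base_pairs) {
  key <- function(entry, chain, seqi) paste(entry, chain, seqi, sep = "\r")
  self <- base_pairs$chain1 == base_pairs$chain2 &
    base_pairs$seq1 == base_pairs$seq2
  bp <- base_pairs[!self, ]
  paired <- unique(c(key(bp$entry_id, bp$chain1, bp$seq1),
                     key(bp$entry_id, bp$chain2, bp$seq2)))
  n_paired <- purrr::imap_int(fragments$nucleotides, function(nts, fi)
    sum(key(fragments$entry_id[[fi]], fragments$chain_id[[fi]],
            nts$seq_index) %in% paired))
  region <- dplyr::case_when(
    n_paired == fragments$k ~ "helix",
    n_paired == 0L ~ "loop",
    TRUE ~ "mixed_HL")
  out <- fragments
  out$n_paired <- n_paired
  out$region <- factor(region, levels = c("helix", "loop", "mixed_HL"))
  out
}

#' Count representative fragments per sequence
#'
#' @param fragments Fragment tibble (equal lengths).
#' @return A tibble with `sequence` and `n`, sorted by decreasing count;
#'   sequences never observed are implicitly zero.
#' @export
sequence_counts <- function(fragments) {
  if (nrow(fragments) > 0L && dplyr::n_distinct(fragments$k) > 1L)
    stop("fragments of mixed lengths")
  fragments |>
    dplyr::count(.data$sequence, sort = TRUE) |>
    tibble::as_tibble()
}
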
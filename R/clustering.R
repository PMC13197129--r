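#' Pairwise Kabsch RMSD matrix
#'
#' Symmetric matrix of superposition RMSDs between all fragments under the
#' canonical atom correspondence of `frame`.
#'
#' @param fragments Fragment tibble (all fragments the same length).
#' @param frame Frame name or list.
#' @return An `n x n` numeric matrix with zero diagonal.
#' @export
rmsd_matrix <- function(fragments, frame) {
  if (nrow(fragments) < 1L) stop("need at least one fragment")
  if (dplyr::n_distinct(fragments$k) > 1L)
    stop("fragments of mixed lengths: ",
         paste(sort(unique(fragments$k)), collapse = ", "))
  coords <- fragment_coords(fragments, frame)
  .rmsd_matrix_coords(coords)
}

.rmsd_matrix_coords <- function(coords) {
  n <- length(coords)
  centered <- purrr::map(coords, ~ sweep(.x, 2L, colMeans(.x)))
  norms <- purrr::map_dbl(centered, ~ sum(.x^2))
  npt <- nrow(coords[[1]])
  m <- matrix(0, n, n)
  if (n > 1L)
    for (i in seq_len(n - 1L))
      for (j in seq(i + 1L, n)) {
        v <- .rmsd_centered(centered[[i]], centered[[j]],
                            norms[[i]] + norms[[j]], npt)
        m[i, j] <- v; m[j, i] <- v
      }
  m
}

# deterministic candidate ordering used throughout the clustering protocol
.fragment_order <- function(fragments)
  order(fragments$entry_id, fragments$chain_id, fragments$start_seq_index)

#' Agglomerative average-linkage clustering of fragments
#'
#' Hierarchical clustering of a fragment RMSD matrix with average (UPGMA)
#' linkage — the inter-cluster distance is the mean of all cross-cluster
#' pairwise RMSDs — cut so that merged clusters have linkage distance at
#' most `threshold`. Each flat cluster is represented by its medoid, the
#' member minimising the mean RMSD to its co-members (ties broken by
#' lowest (entry_id, chain_id, start_seq_index)).
#'
#' @param fragments Fragment tibble.
#' @param frame Frame name or list.
#' @param threshold Linkage cut height, Angstrom.
#' @param dist_matrix Optional precomputed RMSD matrix (skips recomputation).
#' @return An object of class `fragment_clusters`: list with `fragments`
#'   (input plus a `.cluster` integer column), `clusters` (tibble: cluster,
#'   n_members, representative row index into `fragments`), `frame`,
#'   `threshold`.
#' @export
cluster_fragments <- function(fragments, frame, threshold = 0.5,
                              dist_matrix = NULL) {
  fr <- frame_spec(frame)
  n <- nrow(fragments)
  if (n < 1L) stop("need at least one fragment")
  if (is.null(dist_matrix)) dist_matrix <- rmsd_matrix(fragments, fr)
  membership <- if (n == 1L) 1L else {
    tree <- stats::hclust(stats::as.dist(dist_matrix), method = "average")
    stats::cutree(tree, h = threshold)
  }
  rank <- integer(n); rank[.fragment_order(fragments)] <- seq_len(n)
  clusters <- purrr::map(sort(unique(membership)), function(cl) {
    members <- which(membership == cl)
    if (length(members) == 1L) rep_idx <- members
    else {
      sub <- dist_matrix[members, members, drop = FALSE]
      mean_d <- rowSums(sub) / (length(members) - 1L)
      best <- members[mean_d <= min(mean_d) + 1e-12]
      rep_idx <- best[which.min(rank[best])]
    }
    tibble::tibble(cluster = cl, n_members = length(members),
                   representative = rep_idx)
  })
  out <- fragments
  out$.cluster <- as.integer(membership)
  structure(list(fragments = out, clusters = dplyr::bind_rows(clusters),
                 frame = fr$name, threshold = threshold),
            class = "fragment_clusters")
}

#' @export
print.fragment_clusters <- function(x, ...) {
  cat("<fragment_clusters>", nrow(x$fragments), "fragment(s) ->",
      nrow(x$clusters), "cluster(s) | frame", x$frame,
      "| threshold", x$threshold, "A\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.fragment_clusters <- function(x, ...) {
  reps <- x$fragments[x$clusters$representative, ]
  tibble::tibble(
    cluster = x$clusters$cluster,
    n_members = x$clusters$n_members,
    entry_id = reps$entry_id, chain_id = reps$chain_id,
    start_seq_index = reps$start_seq_index, sequence = reps$sequence,
    release_year = reps$release_year)
}

#' @export
glance.fragment_clusters <- function(x, ...) {
  tibble::tibble(n_fragments = nrow(x$fragments),
                 n_clusters = nrow(x$clusters),
                 frame = x$frame, threshold = x$threshold)
}

#' Cluster representatives as a fragment tibble
#'
#' @param x A `fragment_clusters` object.
#' @return The representative (medoid) fragments, ordered deterministically
#'   by (entry_id, chain_id, start_seq_index).
#' @export
cluster_representatives <- function(x) {
  stopifnot(inherits(x, "fragment_clusters"))
  reps <- x$fragments[x$clusters$representative, ]
  reps$.cluster <- NULL
  reps[.fragment_order(reps), ]
}

#' Build a time-resolved non-redundant fragment library
#'
#' The three-stage redundancy-removal protocol. Stage 1: within every
#' structure entry, fragments are clustered at `fine_threshold` and only
#' medoids are kept. Stage 2: within every release year, the surviving
#' entry-level medoids are clustered again at `fine_threshold`. Stage 3:
#' processing years in order (and candidates within a year in the
#' deterministic (entry_id, chain_id, start_seq_index) order), a year
#' medoid counts as a new structural fragment when its minimum RMSD to
#' every previously accepted representative — including candidates
#' accepted earlier in the same year — exceeds `novelty_threshold`;
#' accepted fragments join the reference set immediately. Stage 3 never
#' materialises an all-years distance matrix: each candidate is compared
#' against the accumulated reference coordinates directly.
#'
#' @param fragments Fragment tibble with `release_year` set on every row.
#' @param frame Frame name or list.
#' @param fine_threshold Fine clustering radius, Angstrom (stages 1-2).
#' @param novelty_threshold Novelty radius, Angstrom (stage 3).
#' @return An object of class `growth_series`: list with `series` (tibble:
#'   year, new, cumulative), `representatives` (fragment tibble of all
#'   accepted representatives), `frame`, `k`, `fine_threshold`,
#'   `novelty_threshold`.
#' @export
build_yearly_library <- function(fragments, frame, fine_threshold = 0.5,
                                 novelty_threshold = 1.0) {
  fr <- frame_spec(frame)
  empty <- structure(
    list(series = tibble::tibble(year = integer(), new = integer(),
                                 cumulative = integer()),
         representatives = fragments[0, ], frame = fr$name,
         k = NA_integer_, fine_threshold = fine_threshold,
         novelty_threshold = novelty_threshold),
    class = "growth_series")
  if (nrow(fragments) == 0L) return(empty)
  if (any(is.na(fragments$release_year)))
    stop("every fragment needs a release_year")
  if (dplyr::n_distinct(fragments$k) > 1L)
    stop("fragments of mixed lengths")

  # stage 1: per-entry fine clustering
  entry_meds <- split(fragments, fragments$entry_id) |>
    purrr::map(~ cluster_representatives(
      cluster_fragments(.x, fr, fine_threshold))) |>
    dplyr::bind_rows()

  # stages 2-3 by year
  years <- sort(unique(entry_meds$release_year))
  ref_coords <- list(); reps <- list(); series <- list()
  for (yr in years) {
    ymeds <- entry_meds[entry_meds$release_year == yr, ]
    ymeds <- cluster_representatives(cluster_fragments(ymeds, fr, fine_threshold))
    ycoords <- fragment_coords(ymeds, fr)
    new_count <- 0L
    for (j in seq_len(nrow(ymeds))) {
      xyz <- ycoords[[j]]
      dists <- vapply(ref_coords, function(cc) kabsch_rmsd(xyz, cc), numeric(1))
      if (length(dists) == 0L || min(dists) > novelty_threshold) {
        ref_coords[[length(ref_coords) + 1L]] <- xyz
        reps[[length(reps) + 1L]] <- ymeds[j, ]
        new_count <- new_count + 1L
      }
    }
    series[[length(series) + 1L]] <- tibble::tibble(year = as.integer(yr),
                                                    new = new_count)
  }
  series <- dplyr::bind_rows(series)
  series$cumulative <- cumsum(series$new)
  structure(
    list(series = series, representatives = dplyr::bind_rows(reps),
         frame = fr$name, k = fragments$k[[1]],
         fine_threshold = fine_threshold,
         novelty_threshold = novelty_threshold),
    class = "growth_series")
}

#' @export
print.growth_series <- function(x, ...) {
  cat("<growth_series> frame", x$frame, "| k =", x$k, "|",
      nrow(x$representatives), "non-redundant fragment(s) over",
      nrow(x$series), "year(s)\n")
  print(x$series)
  invisible(x)
}

#' @export
tidy.growth_series <- function(x, ...) x$series

#' @export
glance.growth_series <- function(x, ...) {
  tibble::tibble(frame = x$frame, k = x$k,
                 n_years = nrow(x$series),
                 n_representatives = nrow(x$representatives),
                 fine_threshold = x$fine_threshold,
                 novelty_threshold = x$novelty_threshold)
}

#' Write the per-year growth table as TSV
#'
#' @param x A `growth_series`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_growth_tsv <- function(x, path) {
  stopifnot(inherits(x, "growth_series"))
  out <- dplyr::mutate(x$series, frame = x$frame, k = x$k, .before = 1L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
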
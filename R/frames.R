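#' Reduced atomic reference frames for RNA nucleotides
#'
#' Each frame names the ordered set of atoms used to represent one
#' nucleotide when fragments are superposed. The MxSyBz naming gives the
#' number of mainchain backbone (M), sugar (S) and base (B) atoms. Base
#' atoms differ between purines and pyrimidines but occupy the same
#' positional roles (N9<->N1, C8<->C6, C4<->C2), so coordinate arrays from
#' any two same-length fragments are always comparable position-by-position
#' regardless of sequence.
#'
#' The frames are:
#' \describe{
#'   \item{M6S0B0}{all six mainchain backbone atoms P, O5', C5', C4', C3', O3'}
#'   \item{M0S0B3}{three base atoms: N9, C8, C4 (purines) / N1, C6, C2 (pyrimidines)}
#'   \item{M0S3B0}{three sugar atoms O4', C1', C2'}
#'   \item{M2S0B1}{C4', P and the glycosidic nitrogen N9/N1}
#'   \item{M1S1B1}{C4', C1' and N9/N1}
#'   \item{M0S2B1}{O4', C1' and N9/N1}
#'   \item{FULL15}{the fifteen heavy atoms common to all four nucleotides}
#' }
#'
#' @return A named list; each element has `name`, `atoms_per_nt`, and
#'   character vectors `purine` and `pyrimidine` giving the canonical atom
#'   order.
#' @examples
#' rna_frames()[["M2S0B1"]]
#' @export
rna_frames <- function() {
  mk <- function(name, purine, pyrimidine) {
    stopifnot(length(purine) == length(pyrimidine))
    list(name = name, atoms_per_nt = length(purine),
         purine = purine, pyrimidine = pyrimidine)
  }
  backbone <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")
  full_pur <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
                "C2'", "O2'", "C1'", "N9", "C8", "C4")
  full_pyr <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
                "C2'", "O2'", "C1'", "N1", "C6", "C2")
  list(
    M6S0B0 = mk("M6S0B0", backbone, backbone),
    M0S0B3 = mk("M0S0B3", c("N9", "C8", "C4"), c("N1", "C6", "C2")),
    M0S3B0 = mk("M0S3B0", c("O4'", "C1'", "C2'"), c("O4'", "C1'", "C2'")),
    M2S0B1 = mk("M2S0B1", c("C4'", "P", "N9"), c("C4'", "P", "N1")),
    M1S1B1 = mk("M1S1B1", c("C4'", "C1'", "N9"), c("C4'", "C1'", "N1")),
    M0S2B1 = mk("M0S2B1", c("O4'", "C1'", "N9"), c("O4'", "C1'", "N1")),
    FULL15 = mk("FULL15", full_pur, full_pyr)
  )
}

#' Resolve a frame specification
#'
#' Accepts a frame name (e.g. `"M2S0B1"`) or an already-resolved frame list
#' and returns the frame list.
#'
#' @param frame Frame name or frame list from [rna_frames()].
#' @return A frame list with `name`, `atoms_per_nt`, `purine`, `pyrimidine`.
#' @export
frame_spec <- function(frame) {
  if (is.list(frame) && all(c("name", "purine", "pyrimidine") %in% names(frame)))
    return(frame)
  frames <- rna_frames()
  if (!is.character(frame) || length(frame) != 1L || !frame %in% names(frames))
    stop("unknown frame: ", paste(frame, collapse = ", "),
         " (expected one of ", paste(names(frames), collapse = ", "), ")")
  frames[[frame]]
}

#' Atom names a frame demands for one nucleotide
#'
#' @param frame Frame name or list.
#' @param base_class `"purine"` or `"pyrimidine"`.
#' @return Character vector of atom names in canonical order.
#' @export
frame_atoms <- function(frame, base_class) {
  fr <- frame_spec(frame)
  stopifnot(base_class %in% c("purine", "pyrimidine"))
  if (identical(base_class, "purine")) fr$purine else fr$pyrimidine
}

#' Frame coordinates of fragments
#'
#' Maps each fragment to a `(k * atoms_per_nt) x 3` coordinate matrix in
#' canonical nucleotide-major atom order, the input to RMSD superposition.
#'
#' @param fragments A fragment tibble from [extract_fragments()] or the
#'   synthetic generator.
#' @param frame Frame name or list.
#' @return A list of numeric matrices, one per fragment row.
#' @export
fragment_coords <- function(fragments, frame) {
  fr <- frame_spec(frame)
  purrr::map(fragments$nucleotides, function(nts) {
    mats <- purrr::map2(nts$atoms, nts$base_class, function(atoms, bc) {
      want <- if (identical(bc, "purine")) fr$purine else fr$pyrimidine
      missing <- setdiff(want, rownames(atoms))
      if (length(missing) > 0L)
        stop("fragment nucleotide lacks frame atom(s): ",
             paste(missing, collapse = ", "))
      atoms[want, , drop = FALSE]
    })
    do.call(rbind, mats)
  })
}

#' Export frame definitions as JSON
#'
#' Writes the frame -> purine/pyrimidine atom-list mapping to a JSON file
#' for documentation and cross-language reuse.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frames_json <- function(path) {
  frames <- rna_frames()
  doc <- purrr::map(frames, function(fr)
    list(atoms_per_nt = fr$atoms_per_nt,
         purine = fr$purine, pyrimidine = fr$pyrimidine))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write JSON")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
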
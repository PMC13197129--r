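STANDARD_RNA <- c("A", "C", "G", "U")

.base_class <- function(res_name) {
  dplyr::case_when(
    res_name %in% c("A", "G") ~ "purine",
    res_name %in% c("C", "U") ~ "pyrimidine",
    TRUE ~ NA_character_
  )
}

.normalize_method <- function(method) {
  m <- toupper(trimws(method))
  dplyr::case_when(
    grepl("X-?RAY", m) ~ "xray",
    grepl("ELECTRON MICROSCOPY|CRYO", m) | m == "CRYOEM" | m == "EM" ~ "cryoem",
    TRUE ~ "other"
  )
}

#' Read an entry-metadata sidecar table
#'
#' Tab-separated with a header line and columns `entry_id`, `method`,
#' `resolution`, `release_year`. Method strings are normalised to
#' `xray` / `cryoem` / `other`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per entry.
#' @export
read_entry_meta <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("entry_id", "method", "resolution", "release_year")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("metadata table lacks column(s): ", paste(missing, collapse = ", "))
  tibble::tibble(
    entry_id = as.character(df$entry_id),
    method = .normalize_method(df$method),
    resolution = as.numeric(df$resolution),
    release_year = as.integer(df$release_year)
  )
}

#' Filter structure entries by experimental quality and release date
#'
#' Keeps X-ray and cryo-EM entries with resolution strictly better than
#' `max_resolution` (entries without a reported resolution are dropped)
#' released no later than `cutoff_year`.
#'
#' @param entries Tibble as returned by [read_entry_meta()].
#' @param max_resolution Resolution cutoff in Angstrom (strict `<`).
#' @param cutoff_year Last release year retained (inclusive).
#' @return The filtered tibble.
#' @export
filter_entries <- function(entries, max_resolution = 3.0, cutoff_year = 2023L) {
  entries$method <- .normalize_method(entries$method)
  dplyr::filter(
    entries,
    .data$method %in% c("xray", "cryoem"),
    !is.na(.data$resolution), .data$resolution < max_resolution,
    !is.na(.data$release_year), .data$release_year <= cutoff_year
  )
}

# collapse alternate locations: keep the highest-occupancy conformer,
# ties broken by altloc label (blank/'A' first)
.resolve_altlocs <- function(atom) {
  alt <- ifelse(is.na(atom$alt), "", atom$alt)
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  key <- paste(atom$chain, atom$resno, atom$insert_chr, atom$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  atom <- atom[ord, , drop = FALSE]
  atom[!duplicated(key[ord]), , drop = FALSE]
}

.cif_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    hit <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    val <- trimws(sub(paste0("^", tag, "\\s*"), "", hit[[1]]))
    gsub("^['\"]|['\"]$", "", val)
  }
  entry_id <- grab("_entry.id")
  method <- grab("_exptl.method")
  res <- suppressWarnings(as.numeric(grab("_refine.ls_d_res_high")))
  if (is.na(res))
    res <- suppressWarnings(as.numeric(grab("_em_3d_reconstruction.resolution")))
  # release year: earliest date in the audit revision history block
  year <- NA_integer_
  hist <- grep("_pdbx_audit_revision_history", lines)
  if (length(hist) > 0L) {
    block <- lines[seq(max(hist), min(max(hist) + 50L, length(lines)))]
    dates <- regmatches(block, regexpr("[0-9]{4}-[0-9]{2}-[0-9]{2}", block))
    if (length(dates) > 0L) year <- min(as.integer(substr(dates, 1, 4)))
  }
  tibble::tibble(
    entry_id = entry_id,
    method = ifelse(is.na(method), "other", .normalize_method(method)),
    resolution = res,
    release_year = year
  )
}

#' Read an RNA structure file
#'
#' Parses a PDB or mmCIF file (via \pkg{bio3d}) into one nucleotide record
#' per residue of each RNA chain. Only the first model of multi-model files
#' is used; for alternate locations the highest-occupancy conformer is kept
#' (ties broken by altloc label). Chains are treated as RNA when at least
#' half of their residues carry a C1' atom and at least one carries an O2';
#' protein and DNA chains are dropped (an empty chain set is not an error).
#' Solvent and ligand groups (no C1' and no P) are discarded. Modified
#' nucleotides such as PSU are retained here and excluded later, at
#' fragment extraction.
#'
#' Entry metadata (experimental method, resolution, release year) is read
#' from mmCIF categories where present; for PDB input supply `meta`, either
#' a tibble from [read_entry_meta()] (matched on `entry_id` = file base
#' name) or a one-row list/tibble.
#'
#' @param path Structure file.
#' @param meta Optional metadata (tibble, or path to a metadata TSV).
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @return An object of class `rna_structure`: a list with `meta` (one-row
#'   tibble: entry_id, method, resolution, release_year) and `nucleotides`
#'   (tibble with chain_id, seq_index, icode, res_name, base_class and an
#'   `atoms` list-column of named coordinate matrices).
#' @export
read_structure <- function(path, meta = NULL, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  entry_id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path), ignore.case = TRUE)

  parsed <- tryCatch(
    if (format == "cif")
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE))
    else suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE)),
    error = function(e) stop("failed to parse structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  atom <- parsed$atom
  if (format == "cif") {
    # bio3d's cif reader keeps CIF quoting around atom ids
    for (f in c("elety", "resid", "chain", "alt"))
      atom[[f]] <- gsub("^[\"']|[\"']$", "", atom[[f]])
  }
  atom$insert_chr <- ifelse(is.na(atom$insert), "", as.character(atom$insert))
  atom <- .resolve_altlocs(atom)

  file_meta <- if (format == "cif") .cif_meta(path) else
    tibble::tibble(entry_id = entry_id, method = "other",
                   resolution = NA_real_, release_year = NA_integer_)
  if (is.na(file_meta$entry_id) || !nzchar(file_meta$entry_id))
    file_meta$entry_id <- entry_id

  if (!is.null(meta)) {
    if (is.character(meta)) meta <- read_entry_meta(meta)
    meta <- tibble::as_tibble(meta)
    row <- if ("entry_id" %in% names(meta) && nrow(meta) > 1L)
      dplyr::filter(meta, .data$entry_id == !!file_meta$entry_id) else meta
    if (nrow(row) >= 1L) {
      row <- row[1L, ]
      for (f in c("method", "resolution", "release_year"))
        if (f %in% names(row) && !is.na(row[[f]])) file_meta[[f]] <- row[[f]]
      file_meta$method <- .normalize_method(file_meta$method)
    }
  }

  nts <- .atoms_to_nucleotides(atom)
  structure(list(meta = file_meta, nucleotides = nts), class = "rna_structure")
}

.atoms_to_nucleotides <- function(atom) {
  if (nrow(atom) == 0L)
    return(tibble::tibble(chain_id = character(), seq_index = integer(),
                          icode = character(), res_name = character(),
                          base_class = character(), atoms = list()))
  atom$chain <- ifelse(is.na(atom$chain), "", as.character(atom$chain))
  res_key <- paste(atom$chain, atom$resno, atom$insert_chr, sep = "\r")
  # file order of residues within chains
  first_seen <- !duplicated(res_key)
  res_order <- res_key[first_seen]
  groups <- split(seq_len(nrow(atom)), factor(res_key, levels = res_order))

  rows <- purrr::map(unname(groups), function(idx) {
    sub <- atom[idx, , drop = FALSE]
    xyz <- as.matrix(sub[, c("x", "y", "z")])
    rownames(xyz) <- sub$elety
    xyz <- xyz[!duplicated(sub$elety), , drop = FALSE]
    list(chain_id = sub$chain[[1]], seq_index = as.integer(sub$resno[[1]]),
         icode = sub$insert_chr[[1]], res_name = as.character(sub$resid[[1]]),
         atoms = xyz)
  })
  nts <- tibble::tibble(
    chain_id = purrr::map_chr(rows, "chain_id"),
    seq_index = purrr::map_int(rows, "seq_index"),
    icode = purrr::map_chr(rows, "icode"),
    res_name = purrr::map_chr(rows, "res_name"),
    atoms = purrr::map(rows, "atoms")
  )
  nts$base_class <- .base_class(nts$res_name)
  has_c1 <- purrr::map_lgl(nts$atoms, ~ "C1'" %in% rownames(.x))
  has_o2 <- purrr::map_lgl(nts$atoms, ~ "O2'" %in% rownames(.x))
  has_p <- purrr::map_lgl(nts$atoms, ~ "P" %in% rownames(.x))
  keep_chain <- nts |>
    dplyr::mutate(c1 = has_c1, o2 = has_o2) |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::summarise(rna = mean(.data$c1) >= 0.5 & any(.data$o2)) |>
    dplyr::filter(.data$rna)
  nts <- nts[nts$chain_id %in% keep_chain$chain_id & (has_c1 | has_p), ]
  nts[, c("chain_id", "seq_index", "icode", "res_name", "base_class", "atoms")]
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> entry", x$meta$entry_id,
      "|", nrow(x$nucleotides), "nucleotide(s) in",
      dplyr::n_distinct(x$nucleotides$chain_id), "RNA chain(s)\n")
  invisible(x)
}

#' Extract continuous unmodified RNA fragments
#'
#' Slides a window of `k` nucleotides along every RNA chain and emits each
#' window (stride 1, overlapping) in which all residues are standard
#' A/C/G/U without insertion codes, author numbering is strictly
#' consecutive, consecutive residues are covalently linked
#' (O3'(i)-P(i+1) distance < 2 Angstrom), and every atom demanded by
#' `frame` is present in every nucleotide.
#'
#' @param x An `rna_structure` from [read_structure()] (or a nucleotide
#'   tibble of the same shape, in which case pass `entry_id` and
#'   `release_year`).
#' @param k Fragment length in nucleotides, 2 to 5.
#' @param frame Representation whose atoms must be present; defaults to the
#'   15 common heavy atoms (`"FULL15"`), the strictest requirement.
#' @param entry_id,release_year Used when `x` is a bare nucleotide tibble.
#' @return A fragment tibble: `entry_id`, `chain_id`, `start_seq_index`,
#'   `k`, `sequence`, `release_year`, and a `nucleotides` list-column (one
#'   k-row tibble per fragment).
#' @export
extract_fragments <- function(x, k, frame = "FULL15",
                              entry_id = NULL, release_year = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > 5L) stop("fragment length k must be in 2..5")
  fr <- frame_spec(frame)
  if (inherits(x, "rna_structure")) {
    nts <- x$nucleotides
    if (is.null(entry_id)) entry_id <- x$meta$entry_id
    if (is.null(release_year)) release_year <- x$meta$release_year
  } else nts <- x
  if (is.null(entry_id)) entry_id <- "UNKNOWN"
  if (is.null(release_year)) release_year <- NA_integer_

  out <- list()
  for (ch in unique(nts$chain_id)) {
    cnts <- nts[nts$chain_id == ch, ]
    n <- nrow(cnts)
    if (n < k) next
    nt_ok <- vapply(seq_len(n), function(i) {
      rn <- cnts$res_name[[i]]
      if (!rn %in% STANDARD_RNA || nzchar(cnts$icode[[i]])) return(FALSE)
      want <- frame_atoms(fr, cnts$base_class[[i]])
      all(want %in% rownames(cnts$atoms[[i]]))
    }, logical(1))
    link_ok <- vapply(seq_len(max(0L, n - 1L)), function(i) {
      if (cnts$seq_index[[i + 1L]] != cnts$seq_index[[i]] + 1L) return(FALSE)
      if (nzchar(cnts$icode[[i]]) || nzchar(cnts$icode[[i + 1L]])) return(FALSE)
      o3 <- .atom_xyz(cnts, i, "O3'"); p <- .atom_xyz(cnts, i + 1L, "P")
      if (is.null(o3) || is.null(p)) return(FALSE)
      sqrt(sum((o3 - p)^2)) < 2.0
    }, logical(1))
    for (s in seq_len(n - k + 1L)) {
      win <- s:(s + k - 1L)
      if (!all(nt_ok[win])) next
      if (k > 1L && !all(link_ok[s:(s + k - 2L)])) next
      sub <- cnts[win, c("seq_index", "res_name", "base_class", "atoms")]
      out[[length(out) + 1L]] <- tibble::tibble(
        entry_id = entry_id, chain_id = ch,
        start_seq_index = cnts$seq_index[[s]], k = k,
        sequence = paste(cnts$res_name[win], collapse = ""),
        release_year = as.integer(release_year),
        nucleotides = list(sub))
    }
  }
  if (length(out) == 0L)
    return(tibble::tibble(entry_id = character(), chain_id = character(),
                          start_seq_index = integer(), k = integer(),
                          sequence = character(), release_year = integer(),
                          nucleotides = list()))
  dplyr::bind_rows(out)
}

#' Write a fragment manifest TSV
#'
#' @param fragments Fragment tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fragment_manifest <- function(fragments, path) {
  utils::write.table(
    fragments[, c("entry_id", "chain_id", "start_seq_index", "k",
                  "sequence", "release_year")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
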
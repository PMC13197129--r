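# Internal-coordinate templates for building all-heavy-atom RNA chains.
# Bond lengths (Angstrom) and bond angles (degrees) are standard small-
# molecule values; they are engineering constants of the generator (only
# self-consistency is asserted, e.g. torsion round-trips and covalent
# continuity), not fitted quantities.
.RNA_GEOM <- list(
  bond = c(o3_p = 1.607, p_o5 = 1.593, o5_c5 = 1.440, c5_c4 = 1.510,
           c4_c3 = 1.524, c3_o3 = 1.423, p_op = 1.485, c4_o4 = 1.453,
           o4_c1 = 1.414, c1_c2 = 1.529, c2_o2 = 1.413, c1_n = 1.470,
           n_c = 1.370),
  angle = c(c3_o3_p = 119.7, o3_p_o5 = 104.0, p_o5_c5 = 120.9,
            o5_c5_c4 = 111.5, c5_c4_c3 = 116.0, c4_c3_o3 = 110.6,
            o5_p_op = 107.7, c5_c4_o4 = 109.0, c4_o4_c1 = 109.7,
            o4_c1_c2 = 106.4, c1_c2_o2 = 110.6, o4_c1_n = 108.2,
            c1_n_ca = 126.3, c1_n_cb = 127.0),
  # branch-torsion offsets (degrees) relative to the ring/backbone
  # torsions; signs chosen so the ribose ring closes (C2'-C3' ~ 1.5 A)
  # with the correct D-ribose handedness
  offset = c(o4 = -121, c1 = 121, n = -119, o2 = 121)
)

# sugar ring torsions nu0 (C4'-O4'-C1'-C2'), nu1 (O4'-C1'-C2'-C3') and
# nu4 (C3'-C4'-O4'-C1') from the pseudo-rotation wheel (tau_m = 38 deg;
# P = 18 deg for C3'-endo, 162 deg for C2'-endo)
.PUCKER <- list(
  "C3'-endo" = c(nu0 = 0.0, nu1 = -22.3, nu4 = 22.3),
  "C2'-endo" = c(nu0 = -22.3, nu1 = 36.1, nu4 = 0.0)
)

#' A-form helical torsion set
#'
#' Canonical A-RNA backbone torsions plus the glycosidic chi (anti), in
#' degrees. Used as the default conformation of [build_ideal_chain()];
#' applied uniformly they produce a regular (translationally symmetric)
#' helix.
#'
#' @return Named numeric vector with `alpha`..`zeta` and `chi`.
#' @export
aform_torsions <- function() {
  c(alpha = -68, beta = 178, gamma = 54, delta = 82,
    epsilon = -153, zeta = -71, chi = -158)
}

# natural-extension-reference-frame placement: put D bonded to C with the
# given B-C-D angle and A-B-C-D torsion (degrees, IUPAC sign)
.nerf <- function(a, b, c3, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c3 - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  as.numeric(c3 + cbind(bc, m, n) %*% d2)
}

.wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y <= -180, y + 360, ifelse(y > 180, y - 360, y))
}

.torsion_table <- function(torsions, n) {
  need <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")
  if (is.numeric(torsions) && !is.null(names(torsions))) {
    missing <- setdiff(need, names(torsions))
    if (length(missing) > 0L)
      stop("torsion set lacks: ", paste(missing, collapse = ", "))
    tab <- as.data.frame(as.list(torsions[need]))[rep(1L, n), ]
  } else {
    tab <- as.data.frame(torsions)
    missing <- setdiff(need, names(tab))
    if (length(missing) > 0L)
      stop("torsion table lacks column(s): ", paste(missing, collapse = ", "))
    if (nrow(tab) == 1L) tab <- tab[rep(1L, n), need] else tab <- tab[, need]
    if (nrow(tab) != n)
      stop("torsion table has ", nrow(tab), " rows for ", n, " residues")
  }
  vals <- as.matrix(tab)
  if (any(!is.finite(vals)) || any(vals <= -180) || any(vals > 180))
    stop("torsions must be finite and in (-180, 180]")
  rownames(tab) <- NULL
  tab
}

#' Build an idealised all-heavy-atom RNA chain
#'
#' Constructs an RNA chain from internal coordinates: bond lengths and
#' angles fixed at standard values (one hard-coded table), backbone and
#' glycosidic torsions supplied by the caller. Every nucleotide carries
#' the 15 common heavy atoms, including a 5'-phosphate on the first
#' residue, and consecutive residues satisfy the O3'-P covalent
#' continuity check. Deterministic: identical parameters give identical
#' coordinates.
#'
#' @param sequence Character string over A/C/G/U.
#' @param torsions Named vector (`alpha`..`zeta`, `chi`, applied to every
#'   residue) or a per-residue data frame with those columns, degrees in
#'   (-180, 180].
#' @param pucker Sugar pucker template, `"C3'-endo"` (A-form like) or
#'   `"C2'-endo"`; a single value or one per residue.
#' @param chain_id,start_index Chain id and first author residue number.
#' @return A nucleotide tibble as in [read_structure()]'s `nucleotides`.
#' @examples
#' ch <- build_ideal_chain("GGACU")
#' nrow(ch)  # 5
#' @export
build_ideal_chain <- function(sequence, torsions = aform_torsions(),
                              pucker = "C3'-endo", chain_id = "A",
                              start_index = 1L) {
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(seq_chars)
  if (n == 0L) stop("sequence must be non-empty")
  if (!all(seq_chars %in% STANDARD_RNA))
    stop("sequence must use A/C/G/U only")
  tor <- .torsion_table(torsions, n)
  pucker <- rep(pucker, length.out = n)
  if (!all(pucker %in% names(.PUCKER)))
    stop("pucker must be one of: ", paste(names(.PUCKER), collapse = ", "))

  B <- .RNA_GEOM$bond; A <- .RNA_GEOM$angle; OF <- .RNA_GEOM$offset
  # virtual previous residue to seed the NeRF chain (dropped afterwards)
  prev <- list(c4 = c(-2.00, 1.60, 0.55), c3 = c(-1.20, 0.65, 0.00),
               o3 = c(0, 0, 0))
  prev_tor <- c(epsilon = tor$epsilon[[1]], zeta = tor$zeta[[1]])

  res <- vector("list", n)
  for (i in seq_len(n)) {
    nu <- .PUCKER[[pucker[[i]]]]
    p  <- .nerf(prev$c4, prev$c3, prev$o3, B["o3_p"], A["c3_o3_p"], prev_tor[["epsilon"]])
    o5 <- .nerf(prev$c3, prev$o3, p, B["p_o5"], A["o3_p_o5"], prev_tor[["zeta"]])
    c5 <- .nerf(prev$o3, p, o5, B["o5_c5"], A["p_o5_c5"], tor$alpha[[i]])
    c4 <- .nerf(p, o5, c5, B["c5_c4"], A["o5_c5_c4"], tor$beta[[i]])
    c3 <- .nerf(o5, c5, c4, B["c4_c3"], A["c5_c4_c3"], tor$gamma[[i]])
    o3 <- .nerf(c5, c4, c3, B["c3_o3"], A["c4_c3_o3"], tor$delta[[i]])
    t_op <- dihedral_angle(c5, o5, p, prev$o3)
    op1 <- .nerf(c5, o5, p, B["p_op"], A["o5_p_op"], .wrap180(t_op + 120))
    op2 <- .nerf(c5, o5, p, B["p_op"], A["o5_p_op"], .wrap180(t_op - 120))
    o4 <- .nerf(o5, c5, c4, B["c4_o4"], A["c5_c4_o4"],
                .wrap180(tor$gamma[[i]] + OF[["o4"]]))
    c1 <- .nerf(c5, c4, o4, B["o4_c1"], A["c4_o4_c1"],
                .wrap180(nu[["nu4"]] + OF[["c1"]]))
    c2 <- .nerf(c4, o4, c1, B["c1_c2"], A["o4_c1_c2"], nu[["nu0"]])
    o2 <- .nerf(o4, c1, c2, B["c2_o2"], A["c1_c2_o2"],
                .wrap180(nu[["nu1"]] + OF[["o2"]]))
    nbase <- .nerf(c4, o4, c1, B["c1_n"], A["o4_c1_n"],
                   .wrap180(nu[["nu0"]] + OF[["n"]]))
    ca <- .nerf(o4, c1, nbase, B["n_c"], A["c1_n_ca"], tor$chi[[i]])
    cb <- .nerf(o4, c1, nbase, B["n_c"], A["c1_n_cb"],
                .wrap180(tor$chi[[i]] + 180))
    purine <- seq_chars[[i]] %in% c("A", "G")
    base_names <- if (purine) c("N9", "C8", "C4") else c("N1", "C6", "C2")
    xyz <- rbind(p, op1, op2, o5, c5, c4, o4, c3, o3, c2, o2, c1, nbase, cb, ca)
    rownames(xyz) <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                       "O3'", "C2'", "O2'", "C1'", base_names[1],
                       base_names[2], base_names[3])
    res[[i]] <- xyz
    prev <- list(c4 = c4, c3 = c3, o3 = o3)
    prev_tor <- c(epsilon = tor$epsilon[[i]], zeta = tor$zeta[[i]])
  }
  tibble::tibble(
    chain_id = chain_id,
    seq_index = as.integer(start_index + seq_len(n) - 1L),
    icode = "",
    res_name = seq_chars,
    base_class = .base_class(seq_chars),
    atoms = res
  )
}

#' Wrap a whole built chain as a single fragment
#'
#' Convenience for synthetic chains of length 2-5: the entire chain
#' becomes one fragment row, bypassing window extraction.
#'
#' @param nts Nucleotide tibble, e.g. from [build_ideal_chain()].
#' @param entry_id Entry identifier stamped on the fragment.
#' @param release_year Release year stamped on the fragment.
#' @param chain_id Chain id (defaults to the chain's own).
#' @return A one-row fragment tibble.
#' @export
chain_to_fragment <- function(nts, entry_id, release_year = 2000L,
                              chain_id = NULL) {
  if (is.null(chain_id)) chain_id <- nts$chain_id[[1]]
  tibble::tibble(
    entry_id = entry_id, chain_id = chain_id,
    start_seq_index = nts$seq_index[[1]], k = nrow(nts),
    sequence = paste(nts$res_name, collapse = ""),
    release_year = as.integer(release_year),
    nucleotides = list(nts[, c("seq_index", "res_name", "base_class", "atoms")])
  )
}

# draw one random conformer torsion table (caller manages the RNG state)
.random_conformer_torsions <- function(k) {
  base <- aform_torsions()
  data.frame(
    alpha = stats::runif(k, -180, 180),
    beta = .wrap180(base[["beta"]] + stats::runif(k, -40, 40)),
    gamma = stats::runif(k, -180, 180),
    delta = .wrap180(base[["delta"]] + stats::runif(k, -30, 30)),
    epsilon = .wrap180(base[["epsilon"]] + stats::runif(k, -40, 40)),
    zeta = stats::runif(k, -180, 180),
    chi = stats::runif(k, -180, 180)
  )
}

.random_sequence <- function(k) paste(sample(STANDARD_RNA, k, TRUE), collapse = "")

# apply i.i.d. Gaussian coordinate noise to every atom of a fragment row
.perturb_fragment <- function(frag_row, sigma) {
  nts <- frag_row$nucleotides[[1]]
  nts$atoms <- purrr::map(nts$atoms, function(m)
    m + matrix(stats::rnorm(length(m), 0, sigma), nrow = nrow(m)))
  frag_row$nucleotides <- list(nts)
  frag_row
}

#' Apply a rigid transform to a fragment
#'
#' @param frag_row One-row fragment tibble.
#' @param rotation 3x3 proper rotation matrix (default: random, drawn from
#'   the current RNG state).
#' @param translation Length-3 vector.
#' @return The transformed one-row fragment tibble.
#' @export
rigid_copy <- function(frag_row, rotation = NULL, translation = c(0, 0, 0)) {
  if (is.null(rotation)) rotation <- .random_rotation()
  nts <- frag_row$nucleotides[[1]]
  nts$atoms <- purrr::map(nts$atoms, function(m) {
    out <- m %*% t(rotation)
    out <- sweep(out, 2L, -translation)
    rownames(out) <- rownames(m)
    out
  })
  frag_row$nucleotides <- list(nts)
  frag_row
}

.random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Plant fragment populations with known cluster structure
#'
#' Generates `n_clusters` seed conformers by drawing random torsion sets
#' (rebuilt through [build_ideal_chain()]) until all pairwise frame RMSDs
#' exceed `min_separation`, then emits `members_per_cluster` copies of each
#' seed with i.i.d. Gaussian coordinate noise of standard deviation
#' `intra_noise` per coordinate. Fully deterministic under `seed`.
#'
#' @param n_clusters,members_per_cluster Cluster layout.
#' @param k Fragment length (2-5).
#' @param frame Frame in which separations are measured.
#' @param intra_noise Per-coordinate Gaussian sigma, Angstrom.
#' @param min_separation Minimum pairwise seed RMSD, Angstrom.
#' @param seed Integer RNG seed.
#' @param year Release year stamped on every member.
#' @param max_attempts Resampling budget per seed conformer.
#' @return A list with `fragments` (tibble) and `labels` (integer vector,
#'   ground-truth cluster of each fragment row).
#' @export
plant_fragment_clusters <- function(n_clusters, members_per_cluster, k = 3,
                                    frame = "FULL15", intra_noise = 0.05,
                                    min_separation = 2, seed = 1,
                                    year = 2000L, max_attempts = 500L) {
  withr::with_seed(seed, {
    seeds <- .draw_separated_conformers(n_clusters, k, frame,
                                        min_separation, max_attempts)
    frags <- list(); labels <- integer(0); idx <- 0L
    for (cl in seq_len(n_clusters)) {
      for (m in seq_len(members_per_cluster)) {
        idx <- idx + 1L
        row <- seeds$fragments[cl, ]
        row$entry_id <- sprintf("SYN%04d", idx)
        if (intra_noise > 0) row <- .perturb_fragment(row, intra_noise)
        frags[[idx]] <- row
        labels <- c(labels, cl)
      }
    }
    list(fragments = dplyr::bind_rows(frags), labels = labels)
  })
}

# draw conformers whose pairwise frame RMSD (and RMSD to `against`)
# exceeds min_separation; caller manages RNG
.draw_separated_conformers <- function(n, k, frame, min_separation,
                                       max_attempts = 500L, against = list()) {
  coords <- against; frags <- list()
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      chain <- build_ideal_chain(.random_sequence(k),
                                 .random_conformer_torsions(k))
      frag <- chain_to_fragment(chain, sprintf("SEED%03d", i))
      xyz <- fragment_coords(frag, frame)[[1]]
      sep <- vapply(coords, function(cc) kabsch_rmsd(xyz, cc), numeric(1))
      if (all(sep > min_separation)) {
        coords[[length(coords) + 1L]] <- xyz
        frags[[i]] <- frag
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not generate conformer ", i, " separated by > ",
           min_separation, " A in frame ", frame_spec(frame)$name,
           " within ", max_attempts, " attempts")
  }
  list(fragments = dplyr::bind_rows(frags), coords = coords)
}

.element_of <- function(atom_name) substr(gsub("[^A-Za-z].*$", "", atom_name), 1, 1)

#' Write a structure file (PDB or mmCIF)
#'
#' Serialises a nucleotide tibble (or `rna_structure`) to a
#' standards-conformant file readable by [read_structure()]. Parser edge
#' cases can be injected: `altloc` duplicates selected atoms as A/B
#' alternate locations with given occupancies, and `second_model` appends
#' a second MODEL block that [read_structure()] must ignore.
#'
#' @param x Nucleotide tibble or `rna_structure`.
#' @param path Output file.
#' @param format `"pdb"` or `"cif"`.
#' @param entry_id Entry identifier (written to the file for mmCIF).
#' @param meta Optional list/tibble with `method`, `resolution`,
#'   `release_year` (mmCIF header categories).
#' @param altloc Optional tibble with columns `chain_id`, `seq_index`,
#'   `atom`, `dx`, `dy`, `dz`, `occ_a`, `occ_b`.
#' @param second_model Optional nucleotide tibble written as model 2.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = c("pdb", "cif"),
                            entry_id = "SYN0001", meta = NULL,
                            altloc = NULL, second_model = NULL) {
  format <- match.arg(format)
  nts <- if (inherits(x, "rna_structure")) x$nucleotides else x
  if (format == "pdb")
    .write_pdb(nts, path, altloc = altloc, second_model = second_model)
  else
    .write_cif(nts, path, entry_id = entry_id, meta = meta,
               altloc = altloc, second_model = second_model)
  invisible(path)
}

.pdb_atom_lines <- function(nts, serial_start = 1L, altloc = NULL) {
  lines <- character(0); serial <- serial_start
  fmt <- "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  for (i in seq_len(nrow(nts))) {
    atoms <- nts$atoms[[i]]
    for (an in rownames(atoms)) {
      name4 <- if (nchar(an) < 4L) paste0(" ", an) else an
      xyz <- atoms[an, ]
      alt_row <- NULL
      if (!is.null(altloc))
        alt_row <- altloc[altloc$chain_id == nts$chain_id[[i]] &
                          altloc$seq_index == nts$seq_index[[i]] &
                          altloc$atom == an, ]
      if (!is.null(alt_row) && nrow(alt_row) == 1L) {
        lines <- c(lines,
          sprintf(fmt, serial, name4, "A", nts$res_name[[i]], nts$chain_id[[i]],
                  nts$seq_index[[i]], ifelse(nzchar(nts$icode[[i]]), nts$icode[[i]], " "),
                  xyz[1], xyz[2], xyz[3], alt_row$occ_a, 0, .element_of(an)),
          sprintf(fmt, serial + 1L, name4, "B", nts$res_name[[i]], nts$chain_id[[i]],
                  nts$seq_index[[i]], ifelse(nzchar(nts$icode[[i]]), nts$icode[[i]], " "),
                  xyz[1] + alt_row$dx, xyz[2] + alt_row$dy, xyz[3] + alt_row$dz,
                  alt_row$occ_b, 0, .element_of(an)))
        serial <- serial + 2L
      } else {
        lines <- c(lines,
          sprintf(fmt, serial, name4, " ", nts$res_name[[i]], nts$chain_id[[i]],
                  nts$seq_index[[i]], ifelse(nzchar(nts$icode[[i]]), nts$icode[[i]], " "),
                  xyz[1], xyz[2], xyz[3], 1, 0, .element_of(an)))
        serial <- serial + 1L
      }
    }
  }
  list(lines = lines, serial = serial)
}

.write_pdb <- function(nts, path, altloc = NULL, second_model = NULL) {
  body <- .pdb_atom_lines(nts, 1L, altloc)
  if (is.null(second_model)) {
    lines <- c(body$lines, "TER", "END")
  } else {
    body2 <- .pdb_atom_lines(second_model, 1L, NULL)
    lines <- c("MODEL        1", body$lines, "TER", "ENDMDL",
               "MODEL        2", body2$lines, "TER", "ENDMDL", "END")
  }
  writeLines(lines, path)
}

.write_cif <- function(nts, path, entry_id, meta = NULL, altloc = NULL,
                       second_model = NULL) {
  method_str <- "X-RAY DIFFRACTION"; res <- 2.0; year <- 2000L
  if (!is.null(meta)) {
    meta <- as.list(meta)
    if (!is.null(meta$method))
      method_str <- switch(.normalize_method(meta$method),
                           xray = "X-RAY DIFFRACTION",
                           cryoem = "ELECTRON MICROSCOPY",
                           "SOLUTION NMR")
    if (!is.null(meta$resolution)) res <- meta$resolution
    if (!is.null(meta$release_year)) year <- meta$release_year
  }
  header <- c(
    paste0("data_", entry_id),
    "#",
    paste0("_entry.id ", entry_id),
    paste0("_exptl.method '", method_str, "'"),
    if (!is.na(res)) sprintf("_refine.ls_d_res_high %.2f", res),
    "#",
    "loop_",
    "_pdbx_audit_revision_history.ordinal",
    "_pdbx_audit_revision_history.data_content_type",
    "_pdbx_audit_revision_history.revision_date",
    sprintf("1 'Structure model' %d-01-01", as.integer(year)),
    "#",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num"
  )
  row_of <- function(serial, an, alt, nts, i, xyz, occ, model) {
    sprintf(
      "ATOM %d %s \"%s\" %s %s %s 1 %d %s %.6f %.6f %.6f %.2f 0.00 %d %s %s \"%s\" %d",
      serial, .element_of(an), an, alt, nts$res_name[[i]], nts$chain_id[[i]],
      nts$seq_index[[i]], ifelse(nzchar(nts$icode[[i]]), nts$icode[[i]], "?"),
      xyz[1], xyz[2], xyz[3], occ, nts$seq_index[[i]], nts$res_name[[i]],
      nts$chain_id[[i]], an, model)
  }
  emit_model <- function(nts, model, serial, altloc) {
    lines <- character(0)
    for (i in seq_len(nrow(nts))) {
      atoms <- nts$atoms[[i]]
      for (an in rownames(atoms)) {
        xyz <- atoms[an, ]
        alt_row <- NULL
        if (!is.null(altloc))
          alt_row <- altloc[altloc$chain_id == nts$chain_id[[i]] &
                            altloc$seq_index == nts$seq_index[[i]] &
                            altloc$atom == an, ]
        if (!is.null(alt_row) && nrow(alt_row) == 1L) {
          lines <- c(lines,
            row_of(serial, an, "A", nts, i, xyz, alt_row$occ_a, model),
            row_of(serial + 1L, an, "B", nts, i,
                   xyz + c(alt_row$dx, alt_row$dy, alt_row$dz),
                   alt_row$occ_b, model))
          serial <- serial + 2L
        } else {
          lines <- c(lines, row_of(serial, an, ".", nts, i, xyz, 1, model))
          serial <- serial + 1L
        }
      }
    }
    list(lines = lines, serial = serial)
  }
  m1 <- emit_model(nts, 1L, 1L, altloc)
  lines <- c(header, m1$lines)
  if (!is.null(second_model))
    lines <- c(lines, emit_model(second_model, 2L, m1$serial, NULL)$lines)
  writeLines(c(lines, "#"), path)
}

#' Generate a yearly corpus of synthetic structures with known growth
#'
#' Emulates structure deposition over time: for each scheduled year,
#' `n_novel` new conformers (pairwise frame RMSD above `min_separation`
#' from each other and from every earlier conformer) are written as
#' individual entries, plus `n_copies` redundant entries per year that are
#' rigid-body copies of previously introduced conformers (contributing
#' nothing new). The ground-truth growth series therefore equals the
#' schedule.
#'
#' @param schedule Data frame with strictly increasing `year` and
#'   `n_novel` columns.
#' @param dir Output directory (created if needed); one structure file per
#'   entry plus `meta.tsv`.
#' @param k Fragment length of each entry's single chain.
#' @param frame Frame in which separations are enforced.
#' @param min_separation Minimum conformer separation, Angstrom (must
#'   exceed the 1 Angstrom novelty radius for the ground truth to hold).
#' @param n_copies Redundant rigid-copy entries per year (0 in year 1 if
#'   nothing precedes).
#' @param seed Integer RNG seed.
#' @param format `"pdb"` or `"cif"`.
#' @return A list with `dir`, `metadata` (tibble), `ground_truth`
#'   (tibble: year, new, cumulative), and `fragments` (the generated
#'   fragment tibble, bypassing file round-trip).
#' @export
make_yearly_corpus <- function(schedule, dir, k = 3, frame = "FULL15",
                               min_separation = 1.5, n_copies = 1L,
                               seed = 1, format = c("pdb", "cif")) {
  format <- match.arg(format)
  schedule <- tibble::as_tibble(schedule)
  stopifnot(all(c("year", "n_novel") %in% names(schedule)))
  if (is.unsorted(schedule$year, strictly = TRUE))
    stop("schedule years must be strictly increasing")
  if (min_separation <= 1)
    warning("min_separation <= 1 A: scheduled counts may not be recovered ",
            "at the 1 A novelty radius")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  withr::with_seed(seed, {
    all_coords <- list(); frags <- list(); meta_rows <- list(); idx <- 0L
    introduced <- list()  # fragment rows of all conformers so far
    for (yi in seq_len(nrow(schedule))) {
      yr <- schedule$year[[yi]]
      drawn <- .draw_separated_conformers(schedule$n_novel[[yi]], k, frame,
                                          min_separation, against = all_coords)
      all_coords <- drawn$coords
      year_rows <- list()
      if (schedule$n_novel[[yi]] > 0L)
        for (j in seq_len(nrow(drawn$fragments))) {
          idx <- idx + 1L
          row <- drawn$fragments[j, ]
          row$entry_id <- sprintf("SYN%04d", idx)
          row$release_year <- as.integer(yr)
          year_rows[[length(year_rows) + 1L]] <- row
          introduced[[length(introduced) + 1L]] <- row
        }
      if (length(introduced) > 0L && n_copies > 0L)
        for (cp in seq_len(n_copies)) {
          idx <- idx + 1L
          src <- introduced[[sample.int(length(introduced), 1L)]]
          row <- rigid_copy(src, translation = stats::rnorm(3, 0, 10))
          row$entry_id <- sprintf("SYN%04d", idx)
          row$release_year <- as.integer(yr)
          year_rows[[length(year_rows) + 1L]] <- row
        }
      for (row in year_rows) {
        nts <- row$nucleotides[[1]]
        nts$chain_id <- "A"; nts$icode <- ""
        ext <- if (format == "pdb") "pdb" else "cif"
        fpath <- file.path(dir, paste0(row$entry_id, ".", ext))
        write_structure(nts, fpath, format = format, entry_id = row$entry_id,
                        meta = list(method = "xray", resolution = 2.0,
                                    release_year = row$release_year))
        meta_rows[[length(meta_rows) + 1L]] <- tibble::tibble(
          entry_id = row$entry_id, method = "xray", resolution = 2.0,
          release_year = row$release_year)
        frags[[length(frags) + 1L]] <- row
      }
    }
    metadata <- dplyr::bind_rows(meta_rows)
    utils::write.table(metadata, file.path(dir, "meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ground_truth <- tibble::tibble(
      year = as.integer(schedule$year),
      new = as.integer(schedule$n_novel),
      cumulative = cumsum(as.integer(schedule$n_novel)))
    list(dir = dir, metadata = metadata, ground_truth = ground_truth,
         fragments = dplyr::bind_rows(frags))
  })
}
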
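meta1 <- list(method = "xray", resolution = 2.0, release_year = 2001L)

test_that("a written single-chain structure parses back residue-for-residue", {
  ch <- build_ideal_chain("GGACU")
  for (fmt in c("pdb", "cif")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_structure(ch, path, fmt, meta = meta1)
    st <- read_structure(path, meta = if (fmt == "pdb") meta1 else NULL)
    expect_s3_class(st, "rna_structure")
    expect_identical(nrow(st$nucleotides), 5L)
    expect_identical(dplyr::n_distinct(st$nucleotides$chain_id), 1L)
    expect_identical(st$nucleotides$res_name, c("G", "G", "A", "C", "U"))
    tol <- if (fmt == "pdb") 1e-3 else 1e-6
    err <- max(mapply(function(a, b) max(abs(a[rownames(b), ] - b)),
                      st$nucleotides$atoms, ch$atoms))
    expect_lt(err, tol)
    expect_identical(st$meta$method, "xray")
    expect_equal(st$meta$resolution, 2.0)
    expect_identical(as.integer(st$meta$release_year), 2001L)
  }
})

test_that("writing a parsed structure again is coordinate-idempotent", {
  ch <- build_ideal_chain("ACGU")
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ch, p1, "pdb")
  st1 <- read_structure(p1)
  write_structure(st1, p2, "pdb")
  st2 <- read_structure(p2)
  err <- max(mapply(function(a, b) max(abs(a - b[rownames(a), ])),
                    st1$nucleotides$atoms, st2$nucleotides$atoms))
  expect_lt(err, 1e-3)
})

test_that("only the first model of a multi-model file is used", {
  ch1 <- build_ideal_chain("GGACU")
  ch2 <- build_ideal_chain("GGACU",
                           c(alpha = -60, beta = 160, gamma = 170, delta = 80,
                             epsilon = -150, zeta = -70, chi = 60))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ch1, path, "pdb", second_model = ch2)
  st <- read_structure(path)
  expect_identical(nrow(st$nucleotides), 5L)
  err <- max(mapply(function(a, b) max(abs(a[rownames(b), ] - b)),
                    st$nucleotides$atoms, ch1$atoms))
  expect_lt(err, 1e-3)
})

test_that("alternate locations keep the highest-occupancy conformer, ties to A", {
  ch <- build_ideal_chain("GGACU")
  path <- withr::local_tempfile(fileext = ".pdb")
  al <- tibble::tibble(chain_id = "A", seq_index = 2L, atom = "O2'",
                       dx = 1.2, dy = 0, dz = 0, occ_a = 0.3, occ_b = 0.7)
  write_structure(ch, path, "pdb", altloc = al)
  st <- read_structure(path)
  shift <- unname(st$nucleotides$atoms[[2]]["O2'", 1] - ch$atoms[[2]]["O2'", 1])
  expect_equal(shift, 1.2, tolerance = 1e-2)
  al$occ_a <- 0.5; al$occ_b <- 0.5
  write_structure(ch, path, "pdb", altloc = al)
  st <- read_structure(path)
  shift <- unname(st$nucleotides$atoms[[2]]["O2'", 1] - ch$atoms[[2]]["O2'", 1])
  expect_equal(shift, 0, tolerance = 1e-2)
})

test_that("modified residues are parsed but break fragment windows", {
  ch <- build_ideal_chain("GGACU")
  ch$res_name[3] <- "PSU"; ch$base_class[3] <- NA_character_
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ch, path, "pdb")
  st <- read_structure(path)
  expect_true("PSU" %in% st$nucleotides$res_name)
  expect_identical(nrow(extract_fragments(st, 3, entry_id = "M",
                                          release_year = 2000)), 0L)
  # k = 2 windows away from the modification survive
  expect_identical(nrow(extract_fragments(st, 2, entry_id = "M",
                                          release_year = 2000)), 2L)
})

test_that("non-RNA chains are dropped; no RNA chain is not an error", {
  ch <- build_ideal_chain("GGACU")
  dna <- build_ideal_chain("ACGU", chain_id = "B")
  dna$atoms <- purrr::map(dna$atoms, function(m)
    m[rownames(m) != "O2'", ])   # deoxy: no 2'-OH anywhere
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(dplyr::bind_rows(ch, dna), path, "pdb")
  st <- read_structure(path)
  expect_identical(unique(st$nucleotides$chain_id), "A")
  write_structure(dna, path, "pdb")
  st <- read_structure(path)
  expect_identical(nrow(st$nucleotides), 0L)
  expect_error(read_structure(withr::local_tempfile(fileext = ".pdb")),
               "cannot read")
})

test_that("entry filters implement the strict resolution and year rules", {
  entries <- tibble::tibble(
    entry_id = sprintf("E%02d", 1:6),
    method = c("xray", "xray", "other", "cryoem", "xray", "cryoem"),
    resolution = c(3.0, 2.5, 1.5, 2.9, NA, 2.0),
    release_year = c(2020L, 2020L, 2020L, 2021L, 2019L, 2024L))
  kept <- filter_entries(entries, max_resolution = 3.0, cutoff_year = 2023L)
  expect_identical(kept$entry_id, c("E02", "E04"))
  # resolution exactly at the cutoff is excluded ("better than" read strictly)
  expect_false("E01" %in% kept$entry_id)
  # NMR/other excluded regardless of resolution; missing resolution excluded
  expect_false(any(c("E03", "E05") %in% kept$entry_id))
  # method strings from files normalise before filtering
  entries$method <- c("X-RAY DIFFRACTION", "x-ray", "SOLUTION NMR",
                      "ELECTRON MICROSCOPY", "xray", "cryoem")
  kept2 <- filter_entries(entries, 3.0, 2023L)
  expect_identical(kept2$entry_id, c("E02", "E04"))
})

test_that("fragment extraction emits every clean window and only clean windows", {
  ch <- build_ideal_chain("GGACUA")
  frag_counts <- vapply(2:5, function(k)
    nrow(extract_fragments(ch, k, entry_id = "X", release_year = 2000)),
    integer(1))
  expect_identical(frag_counts, 6L - 2:5 + 1L)
  # numbering gap between positions 3 and 4 of a 6-nt chain
  chg <- ch; chg$seq_index <- c(1L, 2L, 3L, 5L, 6L, 7L)
  fr <- extract_fragments(chg, 2, entry_id = "X", release_year = 2000)
  expect_identical(nrow(fr), 4L)
  expect_identical(fr$start_seq_index, c(1L, 2L, 5L, 6L))
  # an insertion code breaks every window that touches it
  chi <- ch; chi$icode[3] <- "A"
  fri <- extract_fragments(chi, 3, entry_id = "X", release_year = 2000)
  expect_identical(fri$start_seq_index, 4L)  # only the 4-6 window survives
  expect_error(extract_fragments(ch, 6, entry_id = "X", release_year = 2000),
               "2..5")
  expect_error(extract_fragments(ch, 1, entry_id = "X", release_year = 2000),
               "2..5")
})

test_that("extraction respects the frame's required-atom set", {
  ch <- build_ideal_chain("GGACU")
  # drop a base atom from residue 3: FULL15 windows touching it die,
  # backbone-only windows survive
  ch$atoms[[3]] <- ch$atoms[[3]][!rownames(ch$atoms[[3]]) %in% "C8", ]
  expect_identical(nrow(extract_fragments(ch, 3, frame = "FULL15",
                                          entry_id = "X", release_year = 2000)),
                   0L)
  expect_identical(nrow(extract_fragments(ch, 3, frame = "M6S0B0",
                                          entry_id = "X", release_year = 2000)),
                   3L)
})

test_that("random synthetic chains yield fragments satisfying all invariants", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    seqc <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
    ch <- build_ideal_chain(seqc)
    for (k in 2:min(5, n)) {
      fr <- extract_fragments(ch, k, entry_id = "X", release_year = 2000)
      expect_identical(nrow(fr), n - k + 1L)
      expect_fragment_invariants(fr)
    }
  }
})

test_that("fragment manifests round-trip through TSV", {
  frags <- dplyr::bind_rows(make_fragment("GAC"),
                            make_fragment("UUU", entry_id = "SYN0002"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_manifest(frags, path)
  back <- utils::read.delim(path)
  expect_identical(nrow(back), 2L)
  expect_identical(back$sequence, c("GAC", "UUU"))
  expect_identical(back$k, c(3L, 3L))
})
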
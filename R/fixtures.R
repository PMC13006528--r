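# Synthetic fixture generator: small, fully self-contained input bundles
# (query/homolog FASTA, pre-aligned FASTA, toy PDB/mmCIF structures,
# classic-format DSSP files, IUPred2A-style disorder files, BLAST tabular)
# with engineered per-region feature regimes, so the whole pipeline is
# testable offline. File dialects imitate the real-world layouts exactly.

AA_123 <- stats::setNames(names(AA_321)[1:20], unname(AA_321[1:20]))

#' Fixture specification
#'
#' @param length Protein length (>= 10).
#' @param regions List of `list(start=, end=, regime=)` with regime one of
#'   `"taggable"` (diverse columns, coil, exposed, low binding propensity),
#'   `"structured"`, `"conserved"`, `"binding"` (each enforcing the
#'   opposite of one taggable aspect). Non-overlapping, within the protein.
#'   Default: one taggable region spanning the central ~10% of the protein.
#' @param seed RNG seed; bundles are byte-identical for a fixed seed.
#' @return A list of class `FixtureSpec`.
#' @export
fixture_spec <- function(length = 100,
                         regions = list(list(start = round(0.4 * length),
                                             end = round(0.5 * length),
                                             regime = "taggable")),
                         seed = 1) {
  stopifnot(length >= 10)
  regimes <- c("taggable", "structured", "conserved", "binding")
  cover <- integer(0)
  for (r in regions) {
    if (!all(c("start", "end", "regime") %in% names(r)) ||
        !(r$regime %in% regimes)) {
      stop("each region needs start, end and a regime in: ",
           paste(regimes, collapse = ", "))
    }
    if (r$start < 1 || r$end > length || r$start > r$end) {
      stop("region [", r$start, ",", r$end, "] outside 1..", length)
    }
    span <- r$start:r$end
    if (length(intersect(cover, span)) > 0) stop("overlapping regions")
    cover <- c(cover, span)
  }
  structure(list(length = as.integer(length), regions = regions,
                 seed = as.integer(seed)), class = "FixtureSpec")
}

#' Render a toy PDB file
#'
#' Idealized backbone (+CB) geometry along an extended chain or an
#' alpha-helical spiral; parseable by [read_structure()] (and by external
#' DSSP for the helix case). Not physically refined beyond what parsers
#' and the SASA fallback need.
#'
#' @param sequence One-letter amino-acid string.
#' @param geometry `"extended"` or `"helix"`.
#' @param bfactor Value for the B-factor (confidence) column.
#' @param ca_only Emit only CA atoms (for degenerate-input tests).
#' @param file Optional path; when given, the text is written there.
#' @return Character vector of PDB lines (invisibly when `file` is set).
#' @export
make_toy_pdb <- function(sequence, geometry = c("extended", "helix"),
                         bfactor = 90, ca_only = FALSE, file = NULL) {
  geometry <- match.arg(geometry)
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) == 0) stop("zero residues")
  if (!all(aa %in% names(AA_123))) {
    stop("non-standard residue in toy sequence: ",
         paste(setdiff(aa, names(AA_123)), collapse = ", "))
  }
  n <- length(aa)
  ca <- if (geometry == "extended") {
    cbind(3.8 * (seq_len(n) - 1), rep(c(0, 0.6), length.out = n), 0)
  } else {
    ang <- (seq_len(n) - 1) * 100 * pi / 180
    cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * (seq_len(n) - 1))
  }
  if (anyNA(ca) || any(!is.finite(ca))) stop("invalid geometry (NaN coordinates)")
  lines <- character(0)
  serial <- 0L
  emit <- function(name, resname, resno, x, y, z, elem) {
    serial <<- serial + 1L
    lines[length(lines) + 1L] <<- sprintf(
      "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, name, resname, resno, x, y, z, 1.00, bfactor, elem)
  }
  for (i in seq_len(n)) {
    resname <- AA_123[aa[i]]
    p <- ca[i, ]
    if (!ca_only) emit("N", resname, i, p[1] - 1.2, p[2] + 0.5, p[3] - 0.4, "N")
    emit("CA", resname, i, p[1], p[2], p[3], "C")
    if (!ca_only) {
      emit("C", resname, i, p[1] + 1.2, p[2] + 0.5, p[3] + 0.4, "C")
      emit("O", resname, i, p[1] + 1.4, p[2] + 1.7, p[3] + 0.5, "O")
      if (aa[i] != "G") emit("CB", resname, i, p[1], p[2] - 1.2, p[3] + 1.1, "C")
    }
  }
  lines <- c(lines, "TER", "END")
  if (!is.null(file)) { writeLines(lines, file); return(invisible(lines)) }
  lines
}

#' Render the same toy model as minimal mmCIF
#'
#' Emits an `atom_site` loop equivalent to [make_toy_pdb()]'s output, for
#' dialect-equivalence tests.
#' @inheritParams make_toy_pdb
#' @return Character vector of mmCIF lines (invisibly when `file` is set).
#' @export
make_toy_cif <- function(sequence, geometry = c("extended", "helix"),
                         bfactor = 90, file = NULL) {
  pdb_lines <- make_toy_pdb(sequence, geometry, bfactor)
  atom <- pdb_lines[startsWith(pdb_lines, "ATOM")]
  hdr <- c("data_fixture", "#", "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                   "label_atom_id", "label_alt_id",
                                   "label_comp_id", "label_asym_id",
                                   "label_entity_id", "label_seq_id",
                                   "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                                   "Cartn_z", "occupancy", "B_iso_or_equiv",
                                   "pdbx_formal_charge", "auth_seq_id",
                                   "auth_comp_id", "auth_asym_id",
                                   "auth_atom_id", "pdbx_PDB_model_num")))
  rows <- vapply(atom, function(ln) {
    name <- trimws(substr(ln, 13, 16))
    resn <- trimws(substr(ln, 18, 20))
    resi <- trimws(substr(ln, 23, 26))
    sprintf("ATOM %s %s %s . %s A 1 %s ? %.3f %.3f %.3f %.2f %.2f ? %s %s A %s 1",
            trimws(substr(ln, 7, 11)), trimws(substr(ln, 77, 78)),
            name, resn, resi,
            as.numeric(substr(ln, 31, 38)), as.numeric(substr(ln, 39, 46)),
            as.numeric(substr(ln, 47, 54)), as.numeric(substr(ln, 55, 60)),
            as.numeric(substr(ln, 61, 66)), resi, resn, name)
  }, character(1), USE.NAMES = FALSE)
  out <- c(hdr, rows, "#")
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

# Classic fixed-column DSSP rendering of per-residue (aa, ss, acc) rows.
# ss "C" is written as the blank field real DSSP emits for coil.
write_dssp_classic <- function(aa, ss, acc, file) {
  stopifnot(length(aa) == length(ss), length(ss) == length(acc))
  ssf <- ifelse(ss == "C", " ", ss)
  rows <- sprintf("%5d%5d %1s %1s  %1s%17s%4d", seq_along(aa), seq_along(aa),
                  "A", aa, ssf, "", as.integer(acc))
  hdr <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "REFERENCE  synthetic fixture",
    sprintf("%5d  1  0  0  0 TOTAL NUMBER OF RESIDUES", length(aa)),
    paste0("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
           "    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    ",
           "X-CA   Y-CA   Z-CA"))
  writeLines(c(hdr, rows), file)
  invisible(file)
}

# mmCIF-dialect DSSP rendering of the same records.
write_dssp_mmcif <- function(aa, ss, acc, file) {
  hdr <- c("data_fixture", "#", "loop_",
           "_dssp_struct_summary.entry_id",
           "_dssp_struct_summary.label_seq_id",
           "_dssp_struct_summary.label_comp_id",
           "_dssp_struct_summary.secondary_structure",
           "_dssp_struct_summary.accessibility")
  rows <- sprintf("fixture %d %s %s %.1f", seq_along(aa), AA_123[aa],
                  ifelse(ss == "C", ".", ss), as.numeric(acc))
  writeLines(c(hdr, rows, "#"), file)
  invisible(file)
}

#' Generate a complete synthetic input bundle
#'
#' Writes mutually consistent files for one engineered protein: query
#' FASTA, seven-species homolog FASTA, pre-aligned FASTA, toy PDB
#' structure, classic-format DSSP file, IUPred2A-style disorder file, and
#' a BLAST tabular file. In `taggable` regions homolog columns are
#' diversified, the DSSP code is coil, ACC is near SA_max and the binding
#' propensity near 0; `structured`/`conserved`/`binding` regions enforce
#' the opposite of one aspect; the background is conserved, helical,
#' buried, with intermediate binding propensity. Deterministic per seed.
#'
#' @param spec A `FixtureSpec`.
#' @param dir Output directory (created if needed).
#' @return List with `paths` (named file paths), `spec`, `regimes`
#'   (per-position regime labels), `query_id` and `sequence`.
#' @export
make_fixture_protein <- function(spec, dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- spec$length
  regimes <- rep("background", L)
  for (r in spec$regions) regimes[r$start:r$end] <- r$regime
  species <- DEFAULT_SPECIES
  tab <- max_asa_table()
  bundle <- with_seed(spec$seed, {
    qseq <- sample(STANDARD_AA, L, replace = TRUE)
    hom <- matrix(rep(qseq, each = length(species)), nrow = length(species))
    ss <- character(L); acc <- integer(L); br <- numeric(L)
    for (p in seq_len(L)) {
      reg <- regimes[p]
      if (reg == "taggable") {
        # 8 distinct residues across query + homologs -> high column entropy
        pool <- sample(STANDARD_AA, 8)
        qseq[p] <- pool[1]
        hom[, p] <- pool[2:8]
        ss[p] <- "C"
        acc[p] <- as.integer(round(0.9 * tab[qseq[p]]))
        br[p] <- round(stats::runif(1, 0, 0.05), 4)
      } else {
        hom[, p] <- qseq[p]
        if (reg == "background" && stats::runif(1) < 0.1) {
          hom[sample(length(species), 1), p] <- sample(STANDARD_AA, 1)
        }
        ss[p] <- if (reg == "conserved") "C" else "H"
        acc[p] <- as.integer(round(
          (if (reg == "conserved") 0.6 else 0.15) * tab[qseq[p]]))
        br[p] <- round(switch(reg,
                              binding = stats::runif(1, 0.9, 1),
                              conserved = stats::runif(1, 0, 0.1),
                              stats::runif(1, 0.4, 0.6)), 4)
      }
    }
    evalues <- signif(10^stats::runif(length(species), -60, -20), 3)
    bits <- round(stats::runif(length(species), 150, 400), 1)
    list(qseq = qseq, hom = hom, ss = ss, acc = acc, br = br,
         evalues = evalues, bits = bits)
  })
  qid <- sprintf("FIXTURE_L%d_S%d", L, spec$seed)
  qstr <- paste(bundle$qseq, collapse = "")
  hom_ids <- paste0(gsub(" ", "_", species), "|HOM", seq_along(species))
  hom_str <- apply(bundle$hom, 1, paste, collapse = "")
  paths <- list(
    query = file.path(dir, "query.fasta"),
    homologs = file.path(dir, "homologs.fasta"),
    alignment = file.path(dir, "aligned.fasta"),
    structure = file.path(dir, "structure.pdb"),
    dssp = file.path(dir, "structure.dssp"),
    anchor2 = file.path(dir, "anchor2.txt"),
    blast = file.path(dir, "blast.tsv"))
  write_fasta(data.frame(id = qid, sequence = qstr), paths$query)
  write_fasta(data.frame(id = hom_ids, sequence = hom_str), paths$homologs)
  write_fasta(data.frame(id = c(qid, hom_ids),
                         sequence = c(qstr, hom_str)), paths$alignment)
  make_toy_pdb(qstr, "extended", file = paths$structure)
  write_dssp_classic(bundle$qseq, bundle$ss, bundle$acc, paths$dssp)
  writeLines(c("# IUPred2A: context-dependent prediction of protein disorder",
               "# POS\tRES\tIUPRED2\tANCHOR2",
               sprintf("%d\t%s\t%.4f\t%.4f", seq_len(L), bundle$qseq,
                       pmin(1, bundle$br + 0.01), bundle$br)),
             paths$anchor2)
  writeLines(sprintf(
    "%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f",
    qid, hom_ids, 90.0, L, 5L, 0L, 1L, L, 1L, L, bundle$evalues, bundle$bits),
    paths$blast)
  list(paths = paths, spec = spec, regimes = regimes, query_id = qid,
       sequence = qstr)
}
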
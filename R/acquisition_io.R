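# Readers and writers for every external format the pipeline touches:
# FASTA, PDB/mmCIF structures, DSSP output (classic and mmCIF dialects),
# IUPred2A long output (ANCHOR2 column), and BLAST tabular (outfmt 6).

STANDARD_AA <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V")
FLAGGED_AA <- c("X","B","Z","U","*","-")

#' Read a FASTA file into sequence records
#'
#' Sequences are uppercased and whitespace-stripped; record order is
#' preserved. Characters outside the 20 standard one-letter codes are
#' tolerated but flagged with a warning when they fall in `X,B,Z,U,*,-`
#' and rejected otherwise.
#'
#' @param path Path to a FASTA file.
#' @param allow_gaps Logical; suppress the flag warning for `-` (set when
#'   reading aligned FASTA, where gaps are expected).
#' @return A data.frame with columns `id` and `sequence`, one row per record.
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0) stop("empty FASTA file: ", path)
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("not FASTA format: line ", first, " does not start with '>'")
  }
  hdr <- which(startsWith(trimws(lines), ">"))
  # every header must be followed by at least one sequence line before the
  # next header or EOF
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    body <- lines[seq2(hdr[i] + 1L, bounds[i + 1L] - 1L)]
    if (all(trimws(body) == "") || length(body) == 0) {
      stop("FASTA record with empty sequence at line ", hdr[i])
    }
  }
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  sequence <- toupper(gsub("\\s", "", as.character(seqs)))
  bad <- setdiff(unique(unlist(strsplit(sequence, ""))),
                 c(STANDARD_AA, FLAGGED_AA))
  if (length(bad) > 0) {
    stop("invalid sequence characters: ", paste(bad, collapse = ", "))
  }
  flag_set <- if (allow_gaps) setdiff(FLAGGED_AA, "-") else FLAGGED_AA
  flagged <- intersect(unique(unlist(strsplit(sequence, ""))), flag_set)
  if (length(flagged) > 0) {
    warning("non-standard residue codes present (kept, flagged): ",
            paste(flagged, collapse = ", "))
  }
  data.frame(id = unname(ids), sequence = unname(sequence),
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# seq() that yields integer(0) for an empty range instead of counting down
seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

AA_321 <- c(ALA="A",ARG="R",ASN="N",ASP="D",CYS="C",GLN="Q",GLU="E",GLY="G",
            HIS="H",ILE="I",LEU="L",LYS="K",MET="M",PHE="F",PRO="P",SER="S",
            THR="T",TRP="W",TYR="Y",VAL="V",MSE="M",SEC="U")

#' Read a protein structure (PDB or mmCIF)
#'
#' Returns a single chain as a `StructureModel`: residues re-indexed 1..n by
#' order of appearance, the B-factor column exposed as per-residue
#' `confidence` (pLDDT when the model is an AlphaFold prediction), HETATM
#' records and waters excluded. Alternate locations are resolved by the
#' highest-occupancy rule; unresolvable ties and insertion codes are errors.
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`/`.mmcif`) file.
#' @param chain Chain identifier; default is the first protein chain.
#' @param af_model Logical; treat the B-factor column as AlphaFold pLDDT
#'   (values validated to lie in \[0, 100\]).
#' @return A list of class `StructureModel` with elements `chain_id`,
#'   `seq_index`, `aa`, `confidence`, `atoms` (data.frame: seq_index, name,
#'   element, x, y, z).
#' @export
read_structure <- function(path, chain = NULL, af_model = FALSE) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, verbose = FALSE)
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% names(AA_321), , drop = FALSE]
  if (nrow(at) == 0) stop("zero protein residues in ", path)
  chains <- unique(at$chain)
  use_chain <- if (is.null(chain)) chains[1] else chain
  if (!use_chain %in% chains) {
    stop("chain '", use_chain, "' not found; available: ",
         paste(chains, collapse = ", "))
  }
  at <- at[at$chain == use_chain, , drop = FALSE]
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes present in chain ", use_chain, "; not supported")
  }
  # altloc: keep highest occupancy per (resno, atom name); equal-occupancy
  # ambiguity is an error
  alt <- !is.na(at$alt) & at$alt != ""
  if (any(alt)) {
    key <- paste(at$resno, at$elety)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      occ <- at$o[idx]
      if (sum(occ == max(occ)) > 1) {
        stop("altloc ambiguity (equal occupancy) at residue ",
             at$resno[idx[1]], " atom ", at$elety[idx[1]])
      }
      keep[idx[-which.max(occ)]] <- FALSE
    }
    at <- at[keep, , drop = FALSE]
  }
  resno <- unique(at$resno)
  if (is.unsorted(resno, strictly = TRUE)) {
    stop("residue numbering not strictly increasing in chain ", use_chain)
  }
  seq_index <- match(at$resno, resno)
  aa <- unname(AA_321[at$resid[match(resno, at$resno)]])
  conf <- vapply(resno, function(r) at$b[match(r, at$resno)], numeric(1))
  if (af_model && any(!is.na(conf) & (conf < 0 | conf > 100))) {
    stop("pLDDT confidence outside [0, 100]")
  }
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  }
  structure(list(
    chain_id = use_chain,
    seq_index = seq_along(resno),
    aa = aa,
    confidence = unname(conf),
    atoms = data.frame(seq_index = seq_index, name = at$elety,
                       element = elem, x = at$x, y = at$y, z = at$z,
                       stringsAsFactors = FALSE)
  ), class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel: chain", x$chain_id, "-", length(x$seq_index),
      "residues,", nrow(x$atoms), "atoms\n")
  invisible(x)
}

DSSP_CODES <- c("G","H","I","E","B","T","S","P","C")

#' Parse DSSP output
#'
#' Accepts both the classic fixed-column format and the mmCIF dialect
#' (auto-detected from the first non-blank line). Blank secondary-structure
#' fields are normalized to coil (`C`); chain-break rows (`!`) are skipped.
#'
#' @param path DSSP output file.
#' @return data.frame with columns `seq_index`, `aa`, `ss_code`, `acc`.
#' @export
parse_dssp <- function(path) {
  if (!file.exists(path)) stop("DSSP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  first <- trimws(lines[which(trimws(lines) != "")[1]])
  if (startsWith(first, "data_") || grepl("^_dssp", first)) {
    rec <- parse_dssp_mmcif(lines)
  } else {
    rec <- parse_dssp_classic(lines)
  }
  bad <- !rec$ss_code %in% DSSP_CODES
  if (any(bad)) {
    stop("unknown DSSP secondary-structure code(s): ",
         paste(unique(rec$ss_code[bad]), collapse = ", "))
  }
  if (any(rec$acc < 0)) stop("negative DSSP ACC value")
  rec
}

parse_dssp_classic <- function(lines) {
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) stop("malformed DSSP file: residue header not found")
  body_idx <- seq2(hdr[1] + 1L, length(lines))
  out <- vector("list", length(body_idx))
  n <- 0L
  for (i in body_idx) {
    ln <- lines[i]
    if (trimws(ln) == "") next
    aa <- substr(ln, 14, 14)
    if (aa == "!") next                       # chain break
    seqi <- suppressWarnings(as.integer(substr(ln, 6, 10)))
    ss <- substr(ln, 17, 17)
    acc <- suppressWarnings(as.integer(substr(ln, 35, 38)))
    if (is.na(seqi) || is.na(acc)) {
      stop("malformed DSSP residue line at line ", i)
    }
    if (ss == " ") ss <- "C"
    # lowercase letters in the AA column are SS-bonded cysteines
    if (aa %in% letters) aa <- "C"
    n <- n + 1L
    out[[n]] <- list(seq_index = seqi, aa = aa, ss_code = ss, acc = acc)
  }
  if (n == 0L) stop("DSSP file contains no residue rows")
  do.call(rbind.data.frame, c(out[seq_len(n)], stringsAsFactors = FALSE))
}

# Minimal reader for the _dssp_struct_summary loop of mkdssp's mmCIF output.
# No installed R package parses this dialect.
parse_dssp_mmcif <- function(lines) {
  items <- grep("^_dssp_struct_summary\\.", lines)
  if (length(items) == 0) stop("malformed DSSP mmCIF: no _dssp_struct_summary loop")
  fields <- sub("^_dssp_struct_summary\\.", "", trimws(lines[items]))
  need <- c("label_seq_id", "label_comp_id", "secondary_structure", "accessibility")
  if (!all(need %in% fields)) {
    stop("DSSP mmCIF loop missing fields: ",
         paste(setdiff(need, fields), collapse = ", "))
  }
  start <- max(items) + 1L
  rows <- list(); n <- 0L
  for (i in seq2(start, length(lines))) {
    ln <- trimws(lines[i])
    if (ln == "" ) next
    if (startsWith(ln, "_") || startsWith(ln, "loop_") || ln == "#") break
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < length(fields)) {
      stop("malformed DSSP mmCIF row at line ", i)
    }
    val <- stats::setNames(tok[seq_along(fields)], fields)
    aa3 <- val[["label_comp_id"]]
    aa <- if (aa3 %in% names(AA_321)) unname(AA_321[aa3]) else aa3
    ss <- val[["secondary_structure"]]
    if (ss %in% c(".", "?", "~")) ss <- "C"
    acc <- suppressWarnings(as.numeric(val[["accessibility"]]))
    seqi <- suppressWarnings(as.integer(val[["label_seq_id"]]))
    if (is.na(acc) || is.na(seqi)) stop("malformed DSSP mmCIF row at line ", i)
    n <- n + 1L
    rows[[n]] <- list(seq_index = seqi, aa = aa, ss_code = ss, acc = acc)
  }
  if (n == 0L) stop("DSSP mmCIF loop contains no rows")
  do.call(rbind.data.frame, c(rows[seq_len(n)], stringsAsFactors = FALSE))
}

#' Parse IUPred2A/ANCHOR2 per-residue output
#'
#' Accepts the IUPred2A long format (`position residue IUPred-score
#' ANCHOR-score`) or a two-column `position score` file. The ANCHOR2
#' binding propensity is taken from the last (4th) column in long format.
#'
#' @param path IUPred2A long-format or two-column file.
#' @return data.frame with columns `seq_index` and `br` (binding propensity
#'   in \[0,1\]).
#' @export
parse_anchor2 <- function(path) {
  if (!file.exists(path)) stop("ANCHOR2 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & trimws(lines) != ""
  data_lines <- lines[keep]
  if (length(data_lines) == 0) {
    warning("ANCHOR2 file contains no data rows: ", path)
    return(data.frame(seq_index = integer(0), br = numeric(0)))
  }
  tok <- strsplit(trimws(data_lines), "\\s+")
  ncols <- lengths(tok)
  if (all(ncols >= 4)) {
    pos <- as.integer(vapply(tok, `[`, character(1), 1))
    br <- as.numeric(vapply(tok, `[`, character(1), 4))
  } else if (all(ncols == 2)) {
    pos <- as.integer(vapply(tok, `[`, character(1), 1))
    br <- as.numeric(vapply(tok, `[`, character(1), 2))
  } else {
    stop("ANCHOR2 file: expected 4-column IUPred2A long format or ",
         "2-column position/score format")
  }
  if (anyNA(pos) || anyNA(br)) stop("non-numeric value in ANCHOR2 file")
  if (any(br < 0 | br > 1)) {
    stop("ANCHOR2 binding propensity outside [0,1] at position(s): ",
         paste(pos[br < 0 | br > 1], collapse = ", "))
  }
  data.frame(seq_index = pos, br = br)
}

#' Parse BLAST tabular output (outfmt 6)
#'
#' Expects the standard 12 tab-separated columns (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore). The
#' subject species is taken from `species_col` when given (e.g. column 13
#' holding sscinames), otherwise from the subject-id convention
#' `species|accession` with underscores for spaces. An optional
#' `subject_seq_col` names a column holding the full subject sequence.
#'
#' @param path BLAST tabular file.
#' @param species_col Optional 1-based column index with the species name.
#' @param subject_seq_col Optional 1-based column index with the subject
#'   amino-acid sequence.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `subject_species`, `evalue`, `bitscore`, `subject_sequence` (NA when
#'   absent). All rows are returned; no filtering at this layer.
#' @export
parse_blast_tabular <- function(path, species_col = NULL, subject_seq_col = NULL) {
  if (!file.exists(path)) stop("BLAST tabular file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 12) {
    stop("BLAST tabular: expected >= 12 columns (outfmt 6), got ", ncol(tab))
  }
  evalue <- suppressWarnings(as.numeric(tab[[11]]))
  bitscore <- suppressWarnings(as.numeric(tab[[12]]))
  if (anyNA(evalue)) stop("non-numeric E value in BLAST tabular file")
  if (any(evalue < 0)) stop("negative E value in BLAST tabular file")
  if (is.null(species_col) && ncol(tab) >= 13) species_col <- 13L
  species <- if (!is.null(species_col)) {
    tab[[species_col]]
  } else {
    gsub("_", " ", vapply(strsplit(tab[[2]], "\\|"), `[`, character(1), 1))
  }
  sseq <- if (!is.null(subject_seq_col)) toupper(tab[[subject_seq_col]]) else NA_character_
  data.frame(query_id = tab[[1]], subject_id = tab[[2]],
             subject_species = species, evalue = evalue, bitscore = bitscore,
             subject_sequence = sseq, stringsAsFactors = FALSE)
}
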
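# End-to-end workflow: resolve inputs (files or accession), build the four
# feature tracks, score, rank, and write the per-residue TSV and ranked
# site JSON (plus an optional track plot).

#' Run configuration for the scoring pipeline
#'
#' Inputs are either explicit file paths (offline, the default) or a
#' UniProt accession in network mode. Offline mode forbids accession-only
#' input.
#'
#' @param sequence Query FASTA path (required offline).
#' @param alignment Pre-aligned FASTA containing the query row (offline
#'   route), or NULL to align `homologs` with `aligner`.
#' @param dssp DSSP output file for the structure.
#' @param anchor2 IUPred2A/ANCHOR2 per-residue file.
#' @param structure Optional structure file (PDB/mmCIF); used for the
#'   built-in SASA fallback when `dssp` is NULL.
#' @param blast_tab Optional BLAST tabular file (homolog selection route).
#' @param homologs Optional homolog FASTA (aligned with `aligner`).
#' @param accession Optional UniProt accession (network mode only).
#' @param species Species panel for homolog selection.
#' @param scoring A `ScoringConfig`.
#' @param structure_config A `StructureFeatureConfig`.
#' @param aligner Aligner adapter for unaligned homologs.
#' @param out_dir Output directory for written artifacts.
#' @param offline Logical; TRUE (default) forbids network fetches.
#' @param write_plot Logical; also write a feature-track plot (PDF).
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(sequence = NULL, alignment = NULL, dssp = NULL,
                       anchor2 = NULL, structure = NULL, blast_tab = NULL,
                       homologs = NULL, accession = NULL,
                       species = DEFAULT_SPECIES,
                       scoring = scoring_config(),
                       structure_config = structure_feature_config(),
                       aligner = external_aligner_adapter(),
                       out_dir = tempfile("tagsite_out"), offline = TRUE,
                       write_plot = FALSE) {
  if (offline && is.null(sequence) && !is.null(accession)) {
    stop("offline mode forbids accession-only input; supply file paths")
  }
  if (is.null(sequence) && is.null(accession)) {
    stop("either a query FASTA or an accession is required")
  }
  if (is.null(anchor2)) stop("an ANCHOR2 per-residue file is required")
  if (is.null(alignment) && is.null(homologs) && is.null(blast_tab)) {
    stop("an alignment, homolog FASTA, or BLAST tabular file is required")
  }
  if (is.null(dssp) && is.null(structure)) {
    stop("a DSSP file or a structure (for the SASA fallback) is required")
  }
  structure(list(sequence = sequence, alignment = alignment, dssp = dssp,
                 anchor2 = anchor2, structure = structure,
                 blast_tab = blast_tab, homologs = homologs,
                 accession = accession, species = species, scoring = scoring,
                 structure_config = structure_config, aligner = aligner,
                 out_dir = out_dir, offline = offline,
                 write_plot = write_plot),
            class = "RunConfig")
}

#' Run the full tag-site scoring pipeline
#'
#' Reads all inputs, verifies their mutual consistency against the query
#' sequence, computes the entropy, secondary-structure, RSA and
#' disordered-binding feature tracks, scores and ranks positions, and
#' writes a full-precision per-residue TSV plus a ranked-candidate JSON
#' (and an optional plot) under `config$out_dir`. Partial outputs are
#' removed if any stage fails. Runs with identical inputs and config
#' produce byte-identical TSV/JSON.
#'
#' @param config A `RunConfig`.
#' @return The `TagSiteReport`, invisibly; written artifact paths in
#'   `attr(report, "artifacts")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(config$out_dir, "residue_scores.tsv")
  js <- file.path(config$out_dir, "tag_sites.json")
  plotf <- file.path(config$out_dir, "tracks.pdf")
  on_fail <- function(e) {
    unlink(c(tsv, js, plotf))
    stop(e)
  }
  report <- tryCatch({
    # --- query sequence
    if (!is.null(config$sequence)) {
      q <- read_fasta(config$sequence)
      qid <- q$id[1]; qseq <- q$sequence[1]
    } else {
      qp <- fetch_query(config$accession, offline = config$offline)
      qid <- qp$accession; qseq <- qp$sequence
    }
    L <- nchar(qseq)
    qvec <- strsplit(qseq, "")[[1]]

    # --- conservation track
    aln <- if (!is.null(config$alignment)) {
      read_alignment(config$alignment, query_id = qid)
    } else {
      seqs <- data.frame(id = qid, sequence = qseq)
      if (!is.null(config$blast_tab)) {
        hits <- parse_blast_tabular(config$blast_tab, species_col = NULL)
        best <- select_best_hits(hits, config$species)
        hom <- read_fasta(config$homologs)
        hom <- hom[hom$id %in% best$hits$subject_id, , drop = FALSE]
        seqs <- rbind(seqs, hom)
      } else {
        seqs <- rbind(seqs, read_fasta(config$homologs))
      }
      build_msa(seqs, config$aligner, query_id = qid)
    }
    entropy <- entropy_feature(aln)
    if (length(entropy) != L) {
      stop("conservation: alignment query length ", length(entropy),
           " != query sequence length ", L)
    }

    # --- structure tracks
    if (!is.null(config$dssp)) {
      dssp <- parse_dssp(config$dssp)
      mism <- which(dssp$aa != qvec[dssp$seq_index])
      if (length(mism) > 0) {
        stop("structure: DSSP residues differ from query at position(s): ",
             paste(utils::head(dssp$seq_index[mism], 10), collapse = ", "))
      }
      st <- structure_feature_tracks(dssp, L, config$structure_config)
    } else {
      model <- read_structure(config$structure)
      if (paste(model$aa, collapse = "") != qseq) {
        diffs <- which(model$aa != qvec)
        stop("structure: sequence mismatch at position(s): ",
             paste(utils::head(diffs, 10), collapse = ", "))
      }
      sasa <- sasa_shrake_rupley(model)
      tab <- max_asa_table(config$structure_config$max_asa_source)
      st <- list(ss = rep(1, L), rsa = rsa_feature(sasa, model$aa, tab))
      warning("structure: no DSSP input; secondary structure assumed coil, ",
              "RSA from built-in Shrake-Rupley SASA")
    }

    # --- disorder track
    dbr <- dbr_feature(parse_anchor2(config$anchor2), L)

    feats <- assemble_features(entropy, st$ss, st$rsa, dbr)
    scores <- score_residues(feats, config$scoring, aa = qvec)
    rank_sites(scores, accession = qid, config = config$scoring)
  }, error = on_fail)

  ok <- FALSE
  on.exit(if (!ok) unlink(c(tsv, js, plotf)))
  utils::write.table(
    format(report$scores, digits = 15, scientific = FALSE, trim = TRUE),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    accession = report$accession,
    window = report$config$window,
    weights = as.list(report$config$weights),
    candidates = report$candidates,
    terminals = report$terminals
  ), js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (isTRUE(config$write_plot)) plot_tracks(report, plotf)
  ok <- TRUE
  attr(report, "artifacts") <- c(tsv = tsv, json = js,
                                 plot = if (isTRUE(config$write_plot)) plotf)
  invisible(report)
}

#' Plot the feature tracks and windowed minimum score
#'
#' Two panels: the four normalized feature tracks, and the windowed
#' minimum-feature score with the top candidate sites marked by red
#' vertical lines.
#'
#' @param report A `TagSiteReport`.
#' @param file Output file (PDF).
#' @return `file`, invisibly.
#' @export
plot_tracks <- function(report, file) {
  stopifnot(inherits(report, "TagSiteReport"))
  dir.create(dirname(file), showWarnings = FALSE, recursive = TRUE)
  s <- report$scores
  grDevices::pdf(file, width = 9, height = 6)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 1), mar = c(3.5, 4, 2, 1))
  cols <- c(entropy = "#1b9e77", secondary_structure = "#d95f02",
            rsa = "#7570b3", dbr = "#e7298a")
  graphics::plot(s$position, s$entropy, type = "l", col = cols[1],
                 ylim = c(0, 1), xlab = "", ylab = "feature value",
                 main = "Normalized feature tracks")
  for (nm in names(cols)[-1]) {
    graphics::lines(s$position, s[[nm]], col = cols[[nm]])
  }
  graphics::legend("topright", legend = names(cols), col = cols, lty = 1,
                   cex = 0.7, bty = "n")
  graphics::plot(s$position, s$e_windowed, type = "l", lwd = 2,
                 xlab = "position", ylab = "windowed minimum score",
                 main = "Windowed minimum-feature score")
  graphics::abline(v = report$candidates$position, col = "red", lty = 2)
  invisible(file)
}
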
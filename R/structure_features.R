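# Secondary-structure and relative-solvent-accessibility feature tracks,
# plus a built-in Shrake-Rupley SASA fallback for structures without DSSP
# output.

# Maximum accessible surface areas (A^2) per residue type.
# tien2013_theoretical: theoretical maxima; tien2013_empirical: empirical.
MAX_ASA <- list(
  tien2013_theoretical = c(
    A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223, G = 104,
    H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
    T = 172, W = 285, Y = 263, V = 174),
  tien2013_empirical = c(
    A = 121, R = 265, N = 187, D = 187, C = 148, Q = 214, E = 214, G = 97,
    H = 216, I = 195, L = 191, K = 230, M = 203, F = 228, P = 154, S = 143,
    T = 163, W = 264, Y = 255, V = 165)
)

#' Maximum solvent-accessibility table
#' @param source `"tien2013_theoretical"` (default) or `"tien2013_empirical"`.
#' @return Named numeric vector, one-letter code -> SA_max in Angstrom^2.
#' @export
max_asa_table <- function(source = c("tien2013_theoretical",
                                     "tien2013_empirical")) {
  MAX_ASA[[match.arg(source)]]
}

#' Structure-feature configuration
#'
#' Codes `G,H,I,E,P` (helices, strand, polyproline) score 0 — defined
#' structure sensitive to insertion; `C` (coil) scores 1. The codes the
#' binning rule leaves open default to: turn `T` and bend `S` -> 1
#' (loop-like, flexible), isolated beta bridge `B` -> 0 (paired strand
#' residue). All are configurable.
#'
#' @param zero_codes DSSP codes scored 0.
#' @param one_codes DSSP codes scored 1.
#' @param max_asa_source Name of the SA_max table ([max_asa_table()]).
#' @param missing_residue_policy `"score_zero"` (default; positions absent
#'   from DSSP get 0 in both tracks, with a warning) or `"error"`.
#' @return A list of class `StructureFeatureConfig`.
#' @export
structure_feature_config <- function(zero_codes = c("G","H","I","E","P","B"),
                                     one_codes = c("C","T","S"),
                                     max_asa_source = "tien2013_theoretical",
                                     missing_residue_policy = c("score_zero",
                                                                "error")) {
  if (length(intersect(zero_codes, one_codes)) > 0) {
    stop("zero_codes and one_codes overlap: ",
         paste(intersect(zero_codes, one_codes), collapse = ", "))
  }
  structure(list(zero_codes = zero_codes, one_codes = one_codes,
                 max_asa_source = max_asa_source,
                 missing_residue_policy = match.arg(missing_residue_policy)),
            class = "StructureFeatureConfig")
}

#' Secondary-structure feature of a DSSP code
#'
#' @param ss_code Character vector of normalized DSSP codes.
#' @param config A `StructureFeatureConfig`.
#' @return 0 for insertion-sensitive codes, 1 for coil-like codes.
#' @export
ss_feature <- function(ss_code, config = structure_feature_config()) {
  known <- c(config$zero_codes, config$one_codes)
  bad <- setdiff(unique(ss_code), known)
  if (length(bad) > 0) {
    stop("unknown secondary-structure code(s): ", paste(bad, collapse = ", "))
  }
  as.numeric(ss_code %in% config$one_codes)
}

#' Relative solvent accessibility
#'
#' `RSA = ACC / SA_max(aa)`, clamped to 1 (DSSP ACC can exceed the
#' tabulated maximum for extended conformations).
#'
#' @param acc Solvent-accessible surface area, Angstrom^2 (>= 0).
#' @param aa One-letter residue code(s), standard 20 only.
#' @param table SA_max table ([max_asa_table()]).
#' @return RSA in \[0,1\].
#' @export
rsa_feature <- function(acc, aa, table = max_asa_table()) {
  if (any(acc < 0)) stop("negative solvent accessibility")
  bad <- setdiff(unique(aa), names(table))
  if (length(bad) > 0) {
    stop("residue(s) not in SA_max table: ", paste(bad, collapse = ", "))
  }
  pmin(acc / unname(table[aa]), 1)
}

# van der Waals radii (A) by element for the SASA fallback
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
               SE = 1.90)

# Deterministic quasi-uniform points on the unit sphere (golden spiral);
# no RNG involved, so SASA is reproducible for fixed n.
sphere_points <- function(n) {
  k <- seq_len(n) - 1L
  z <- 1 - (2 * k + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- k * pi * (3 - sqrt(5))
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Built-in per-residue SASA for when DSSP output is unavailable. Each
#' atom's accessible fraction is estimated on a deterministic golden-spiral
#' point set; a test point is buried if it lies within the solvent-expanded
#' radius of any other atom.
#'
#' @param model A `StructureModel` with an all-atom (at least backbone)
#'   representation; CA-only traces are rejected.
#' @param probe_radius Solvent probe radius, Angstrom (default 1.4).
#' @param n_points Test points per atom (default 960).
#' @return Numeric vector of per-residue SASA (Angstrom^2), length =
#'   number of residues.
#' @export
sasa_shrake_rupley <- function(model, probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(model, "StructureModel"))
  at <- model$atoms
  if (nrow(at) == 0) stop("empty structure")
  if (all(at$name == "CA")) stop("all-atom model required (CA-only trace)")
  elem <- toupper(at$element)
  radii <- VDW_RADII[elem]
  radii[is.na(radii)] <- 1.70
  radii <- unname(radii) + probe_radius
  xyz <- as.matrix(at[, c("x", "y", "z")])
  pts <- sphere_points(n_points)
  n_atoms <- nrow(at)
  atom_sasa <- numeric(n_atoms)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n_atoms)) {
    # neighbors that can possibly occlude atom i
    nb <- which(d2[i, ] < (radii[i] + radii)^2 & seq_len(n_atoms) != i)
    if (length(nb) == 0) {
      atom_sasa[i] <- 4 * pi * radii[i]^2
      next
    }
    test <- sweep(pts * radii[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (test[, 1] - xyz[j, 1])^2 + (test[, 2] - xyz[j, 2])^2 +
             (test[, 3] - xyz[j, 3])^2
      free <- free & dj2 > radii[j]^2
      if (!any(free)) break
    }
    atom_sasa[i] <- 4 * pi * radii[i]^2 * sum(free) / n_points
  }
  vapply(model$seq_index, function(r) sum(atom_sasa[at$seq_index == r]),
         numeric(1))
}

#' Secondary-structure and RSA feature tracks from DSSP records
#'
#' DSSP records must already be re-indexed to query positions (1-based).
#' Positions absent from the records are handled per the configured
#' missing-residue policy.
#'
#' @param dssp data.frame from [parse_dssp()], `seq_index` in 1..query_length.
#' @param query_length Length of the query sequence.
#' @param config A `StructureFeatureConfig`.
#' @return List with numeric tracks `ss` and `rsa`, each of length
#'   `query_length`, values in \[0,1\].
#' @export
structure_feature_tracks <- function(dssp, query_length,
                                     config = structure_feature_config()) {
  stopifnot(is.data.frame(dssp), query_length >= 1)
  if (anyDuplicated(dssp$seq_index)) {
    stop("duplicate DSSP seq_index: ",
         paste(unique(dssp$seq_index[duplicated(dssp$seq_index)]),
               collapse = ", "))
  }
  if (any(dssp$seq_index < 1 | dssp$seq_index > query_length)) {
    stop("DSSP seq_index outside 1..", query_length)
  }
  missing <- setdiff(seq_len(query_length), dssp$seq_index)
  if (length(missing) > 0) {
    if (config$missing_residue_policy == "error") {
      stop("residue(s) missing from DSSP output: ",
           paste(missing, collapse = ", "))
    }
    warning("residue(s) missing from DSSP output scored 0: ",
            paste(missing, collapse = ", "))
  }
  ss <- numeric(query_length)
  rsa <- numeric(query_length)
  tab <- max_asa_table(config$max_asa_source)
  ss[dssp$seq_index] <- ss_feature(dssp$ss_code, config)
  rsa[dssp$seq_index] <- rsa_feature(dssp$acc, dssp$aa, tab)
  list(ss = ss, rsa = rsa)
}
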
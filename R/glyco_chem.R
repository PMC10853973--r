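# Monoisotopic residue masses and hydrophobicity scales used throughout.
# All masses in Da; residue mass = free molecule minus water.

.MONOSACCHARIDE_RESIDUE_MASS <- c(
  hexnac = 203.07937,
  hex    = 162.05282,
  neuac  = 291.09542,
  neugc  = 307.09033,
  fuc    = 146.05791
)

.MONOSACCHARIDE_NAMES <- c(
  HexNAc = "hexnac", Hex = "hex", NeuAc = "neuac", NeuGc = "neugc",
  Fuc = "fuc", dHex = "fuc"
)

.AA_RESIDUE_MASS <- c(
  G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,
  V = 99.06841,  T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.WATER_MASS  <- 18.010565
.PROTON_MASS <- 1.00727646

# Kyte-Doolittle residue hydropathy index.
.KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Default fixed modifications
#'
#' Carbamidomethylation of cysteine (+57.02146 Da), matching iodoacetamide
#' alkylation, is the only default fixed modification. Supply a different
#' named numeric vector (names are residue letters) to override.
#'
#' @return Named numeric vector of per-residue mass offsets in Da.
#' @export
default_fixed_mods <- function() c(C = 57.02146)

#' Parse a glycan composition string
#'
#' Parses composition strings of the form `"HexNAc(4)Hex(5)NeuAc(2)"` into
#' monosaccharide counts. Recognized names are HexNAc, Hex, NeuAc, NeuGc and
#' Fuc (dHex is accepted as an alias of Fuc); matching is case-sensitive.
#' Absent monosaccharides get count 0.
#'
#' @param text Composition string, e.g. `"HexNAc(4)Hex(5)NeuAc(2)"`.
#' @return A `glycan_composition` object: named integer vector with elements
#'   `hexnac`, `hex`, `neuac`, `neugc`, `fuc`.
#' @examples
#' parse_glycan_composition("HexNAc(4)Hex(5)NeuAc(2)")
#' @export
parse_glycan_composition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (!nzchar(text)) stop("empty glycan composition string")
  tokens <- gregexpr("([A-Za-z]+)\\((-?[0-9.]+)\\)", text, perl = TRUE)[[1]]
  matched <- regmatches(text, gregexpr("([A-Za-z]+)\\((-?[0-9.]+)\\)", text,
                                       perl = TRUE))[[1]]
  if (tokens[1] == -1L || sum(attr(tokens, "match.length")) != nchar(text))
    stop("glycan composition does not match Name(count) token syntax: ",
         sQuote(text))
  counts <- c(hexnac = 0L, hex = 0L, neuac = 0L, neugc = 0L, fuc = 0L)
  for (tok in matched) {
    name  <- sub("\\(.*$", "", tok)
    count <- sub("^.*\\(", "", sub("\\)$", "", tok))
    if (!name %in% names(.MONOSACCHARIDE_NAMES))
      stop("unrecognized monosaccharide ", sQuote(name), " in ", sQuote(text))
    n <- suppressWarnings(as.numeric(count))
    if (is.na(n) || n < 0 || n != round(n))
      stop("invalid count ", sQuote(count), " for ", sQuote(name))
    slot <- .MONOSACCHARIDE_NAMES[[name]]
    counts[[slot]] <- counts[[slot]] + as.integer(n)
  }
  structure(counts, class = "glycan_composition")
}

#' Format a glycan composition back to its string form
#'
#' Inverse of [parse_glycan_composition()]: zero counts are omitted and the
#' canonical ordering HexNAc, Hex, NeuAc, NeuGc, Fuc is used.
#'
#' @param comp A `glycan_composition`.
#' @return Composition string.
#' @export
format_glycan_composition <- function(comp) {
  comp <- as_glycan_composition(comp)
  canonical <- c(hexnac = "HexNAc", hex = "Hex", neuac = "NeuAc",
                 neugc = "NeuGc", fuc = "Fuc")
  parts <- vapply(names(canonical), function(s) {
    if (comp[[s]] > 0) sprintf("%s(%d)", canonical[[s]], comp[[s]]) else ""
  }, character(1))
  paste0(parts[nzchar(parts)], collapse = "")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan composition> ", format_glycan_composition(x), "\n", sep = "")
  invisible(x)
}

as_glycan_composition <- function(comp) {
  if (inherits(comp, "glycan_composition")) return(comp)
  if (is.character(comp)) return(parse_glycan_composition(comp))
  stopifnot(is.numeric(comp))
  slots <- c("hexnac", "hex", "neuac", "neugc", "fuc")
  out <- c(hexnac = 0L, hex = 0L, neuac = 0L, neugc = 0L, fuc = 0L)
  stopifnot(!is.null(names(comp)), all(names(comp) %in% slots))
  out[names(comp)] <- as.integer(comp)
  if (any(out < 0)) stop("negative monosaccharide count")
  structure(out, class = "glycan_composition")
}

#' Monoisotopic mass of a glycan
#'
#' Sum of monosaccharide residue masses (residue = free monosaccharide minus
#' water): HexNAc 203.07937, Hex 162.05282, NeuAc 291.09542, NeuGc 307.09033,
#' Fuc 146.05791 Da. The mass is strictly additive in the counts.
#'
#' @param comp A `glycan_composition` or a composition string.
#' @return Monoisotopic mass in Da.
#' @examples
#' glycan_mass("HexNAc(2)Hex(3)")  # 892.3172
#' @export
glycan_mass <- function(comp) {
  comp <- as_glycan_composition(comp)
  sum(unclass(comp) * .MONOSACCHARIDE_RESIDUE_MASS[names(comp)])
}

check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  if (!nzchar(sequence)) stop("empty peptide sequence")
  letters <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters, names(.AA_RESIDUE_MASS))
  if (length(bad))
    stop("non-canonical amino acid letter(s): ", paste(bad, collapse = ", "))
  letters
}

#' Monoisotopic mass of a peptide
#'
#' Sum of amino-acid residue masses plus one water (18.010565 Da) plus fixed
#' modification offsets. The default fixed modification is
#' carbamidomethyl-Cys (+57.02146 Da per C).
#'
#' @param sequence Upper-case amino-acid string (20 canonical letters).
#' @param fixed_mods Named numeric vector of per-residue mass offsets;
#'   see [default_fixed_mods()].
#' @return Monoisotopic mass in Da.
#' @examples
#' peptide_mass("ENGTISR")  # 775.38242
#' @export
peptide_mass <- function(sequence, fixed_mods = default_fixed_mods()) {
  letters <- check_sequence(sequence)
  mass <- sum(.AA_RESIDUE_MASS[letters]) + .WATER_MASS
  if (length(fixed_mods)) {
    counts <- table(factor(letters, levels = names(fixed_mods)))
    mass <- mass + sum(as.numeric(counts) * fixed_mods)
  }
  mass
}

#' Construct a glycopeptide species
#'
#' The unit of all per-species analysis: peptide sequence, glycan composition
#' and precursor charge. Species differing only in charge are distinct
#' analysis points.
#'
#' @param sequence Peptide sequence.
#' @param glycan Glycan composition (string or `glycan_composition`).
#' @param charge Positive integer precursor charge.
#' @param retention_time Optional retention time in minutes.
#' @param observed_mz Optional observed m/z in Th.
#' @param fixed_mods Fixed modifications passed to [peptide_mass()].
#' @return A `glycopeptide_species` object.
#' @export
glycopeptide_species <- function(sequence, glycan, charge,
                                 retention_time = NA_real_,
                                 observed_mz = NA_real_,
                                 fixed_mods = default_fixed_mods()) {
  check_sequence(sequence)
  glycan <- as_glycan_composition(glycan)
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  structure(list(sequence = sequence, glycan = glycan, charge = charge,
                 retention_time = retention_time, observed_mz = observed_mz,
                 fixed_mods = fixed_mods),
            class = "glycopeptide_species")
}

#' @export
print.glycopeptide_species <- function(x, ...) {
  cat(sprintf("<glycopeptide> %s-%s %d+\n", x$sequence,
              format_glycan_composition(x$glycan), x$charge))
  invisible(x)
}

#' Species identity key
#'
#' @param species A `glycopeptide_species`.
#' @return Character key `(sequence, composition, charge)`.
#' @export
species_key <- function(species) {
  paste(species$sequence, format_glycan_composition(species$glycan),
        species$charge, sep = "|")
}

#' Theoretical precursor m/z
#'
#' `(peptide mass + glycan mass + z * 1.00727646) / z`, all monoisotopic.
#'
#' @param species A `glycopeptide_species`.
#' @return m/z in Th.
#' @export
theoretical_mz <- function(species) {
  stopifnot(inherits(species, "glycopeptide_species"))
  z <- species$charge
  if (z < 1L) stop("charge must be >= 1")
  (peptide_mass(species$sequence, species$fixed_mods) +
     glycan_mass(species$glycan) + z * .PROTON_MASS) / z
}

#' Number of mobile protons
#'
#' Charge minus the number of basic sites, counting Lys, Arg, His residues
#' and the N-terminus. The value may be negative (proton-deficient species);
#' no clamping is applied.
#'
#' @param species A `glycopeptide_species`.
#' @return Integer count (possibly negative).
#' @examples
#' mobile_proton_count(glycopeptide_species("ENGTISR", "HexNAc(2)Hex(5)", 2))
#' @export
mobile_proton_count <- function(species) {
  stopifnot(inherits(species, "glycopeptide_species"))
  letters <- strsplit(species$sequence, "")[[1]]
  basic <- sum(letters %in% c("K", "R", "H")) + 1L
  species$charge - basic
}

#' Peptide hydrophobicity index
#'
#' Residue-additive hydrophobicity: the sum of a per-residue scale over the
#' sequence. The default scale is Kyte-Doolittle. Only the ordering of the
#' values is meaningful across scales; absolute values are scale units.
#'
#' @param sequence Peptide sequence.
#' @param scale Named numeric vector covering all 20 canonical residues.
#' @return Hydrophobicity in scale units.
#' @examples
#' hydrophobicity("III")  # 13.5
#' @export
hydrophobicity <- function(sequence, scale = kyte_doolittle_scale()) {
  letters <- check_sequence(sequence)
  missing <- setdiff(names(.AA_RESIDUE_MASS), names(scale))
  if (length(missing))
    stop("hydrophobicity scale lacks residue(s): ",
         paste(missing, collapse = ", "))
  sum(scale[letters])
}

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector of per-residue hydropathy values.
#' @export
kyte_doolittle_scale <- function() .KYTE_DOOLITTLE

#' Structural glycan features
#'
#' Derives the glycan-level covariates: number of sialic acids
#' (NeuAc + NeuGc), number of fucoses, high-mannose flag
#' (HexNAc(2)Hex(>=5), no sialic acid or fucose) and an antenna-count
#' heuristic `max(0, hexnac - 2)` for non-high-mannose structures. The
#' heuristic ignores bisecting GlcNAc; see the package vignette.
#'
#' @param comp A `glycan_composition` or composition string.
#' @return List with `n_sialic`, `n_fucose`, `n_antennae`, `is_high_mannose`.
#' @export
glycan_features <- function(comp) {
  comp <- as_glycan_composition(comp)
  is_hm <- comp[["hexnac"]] == 2L && comp[["hex"]] >= 5L &&
    (comp[["neuac"]] + comp[["neugc"]] + comp[["fuc"]]) == 0L
  list(
    n_sialic  = comp[["neuac"]] + comp[["neugc"]],
    n_fucose  = comp[["fuc"]],
    n_antennae = if (is_hm) 0L else max(0L, comp[["hexnac"]] - 2L),
    is_high_mannose = is_hm
  )
}

#' Full structural feature vector for one species
#'
#' Computes every covariate used by the GLM, lasso and smart-CE stages:
#' m/z, total/peptide/glycan masses, peptide-only m/z (peptide backbone at
#' the species charge), hydrophobicity, charge, mobile protons, glycan
#' features, glycosylation-site position fraction (first N-X-S/T sequon,
#' 0 if none), peptide length, and the 20 amino-acid and 5 monosaccharide
#' counts.
#'
#' @param species A `glycopeptide_species`.
#' @param scale Hydrophobicity scale.
#' @return Named numeric vector (one row of the feature matrix).
#' @export
feature_vector <- function(species, scale = kyte_doolittle_scale()) {
  stopifnot(inherits(species, "glycopeptide_species"))
  pm <- peptide_mass(species$sequence, species$fixed_mods)
  gm <- glycan_mass(species$glycan)
  z  <- species$charge
  gf <- glycan_features(species$glycan)
  letters <- strsplit(species$sequence, "")[[1]]
  aa_counts <- as.numeric(table(factor(letters,
                                       levels = names(.AA_RESIDUE_MASS))))
  names(aa_counts) <- paste0("aa_", names(.AA_RESIDUE_MASS))
  mono <- as.numeric(unclass(species$glycan))
  names(mono) <- paste0("mono_", names(species$glycan))
  sequon <- regexpr("N[^P][ST]", species$sequence, perl = TRUE)
  pos_frac <- if (sequon > 0) (sequon - 1) / max(1L, length(letters) - 1L)
              else 0
  c(
    mz = (pm + gm + z * .PROTON_MASS) / z,
    total_mass = pm + gm,
    peptide_mass = pm,
    glycan_mass = gm,
    peptide_only_mz = (pm + z * .PROTON_MASS) / z,
    hydrophobicity = hydrophobicity(species$sequence, scale),
    charge = z,
    mobile_protons = mobile_proton_count(species),
    n_sialic = gf$n_sialic,
    n_fucose = gf$n_fucose,
    n_antennae = gf$n_antennae,
    glycosite_position_fraction = pos_frac,
    peptide_length = length(letters),
    aa_counts,
    mono
  )
}

#' Feature matrix for a list of species
#'
#' @param species_list List of `glycopeptide_species`.
#' @param scale Hydrophobicity scale.
#' @return Data frame, one row per species, with a `species_key` column
#'   followed by all [feature_vector()] columns.
#' @export
feature_table <- function(species_list, scale = kyte_doolittle_scale()) {
  stopifnot(length(species_list) >= 1L)
  rows <- t(vapply(species_list, feature_vector,
                   feature_vector(species_list[[1]], scale), scale = scale))
  out <- as.data.frame(rows)
  out$species_key <- vapply(species_list, species_key, character(1))
  out[, c("species_key", setdiff(names(out), "species_key"))]
}

#' Read a species list file
#'
#' Tab-delimited file with columns `sequence`, `glycan_composition`,
#' `charge` and optional `retention_time_min`, `observed_mz` — the content
#' of a targeted inclusion list.
#'
#' @param path File path.
#' @return List of `glycopeptide_species`.
#' @export
read_species_list <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  required <- c("sequence", "glycan_composition", "charge")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("species list lacks column(s): ", paste(missing, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    glycopeptide_species(
      tab$sequence[i], tab$glycan_composition[i], tab$charge[i],
      retention_time = if ("retention_time_min" %in% names(tab))
        tab$retention_time_min[i] else NA_real_,
      observed_mz = if ("observed_mz" %in% names(tab))
        tab$observed_mz[i] else NA_real_
    )
  })
}
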
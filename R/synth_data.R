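# Synthetic CE-sweep experiment generator. Emulates the statistical
# structure the analysis assumes: per-species Gaussian score-vs-energy
# responses whose centers are linear in m/z plus structural covariates,
# engine personas ranging from peptide-centric to glycan-centric (glycan
# fragmentation needs about half the energy of peptide-backbone
# fragmentation), lognormal peak scores with detection-threshold
# missingness, and occasional duplicate identifications within a run.

#' Engine persona parameters
#'
#' The two archetypes span the observed range of search-engine behavior.
#' The peptide-centric persona's optimum tracks the instrument reference
#' line (slope 0.0607 eV/Th) with a marked hydrophobicity effect; the
#' glycan-centric persona sits at about half that energy, reacts strongly
#' to mobile protons and is lowered by glycan (sialic-acid) mass. All
#' defaults can be overridden via `...`.
#'
#' @param name `"peptide_centric"` or `"glycan_centric"`.
#' @param ... Named overrides of any parameter field.
#' @return A `persona_params` list: `name`, `intercept` (eV), `slope_mz`
#'   (eV/Th), `coef_hydrophobicity` (eV per index unit),
#'   `coef_mobile_protons` (eV per proton), `coef_glycan_mass` (eV/Da),
#'   `optimum_noise_sd` (eV), `curve_sigma_mean` (eV), `curve_sigma_cv`,
#'   `peak_score_log_mean`, `peak_score_log_sd`, `detection_threshold`,
#'   `multiplicative_score_noise_sd`.
#' @export
persona_params <- function(name = c("peptide_centric", "glycan_centric"),
                           ...) {
  name <- match.arg(name)
  p <- if (name == "peptide_centric") {
    list(name = name,
         intercept = 13.571, slope_mz = 85 / 1400,
         coef_hydrophobicity = 0.5, coef_mobile_protons = -1.5,
         coef_glycan_mass = 0,
         optimum_noise_sd = 3, curve_sigma_mean = 18, curve_sigma_cv = 0.2,
         peak_score_log_mean = log(800), peak_score_log_sd = 0.9,
         detection_threshold = 100, multiplicative_score_noise_sd = 0.05)
  } else {
    # intercept calibrated so that, at the default cohort's covariate
    # means, the glycan-centric optimum is half the peptide-centric one at
    # matched m/z (glycan fragmentation needs about half the energy)
    list(name = name,
         intercept = 15.55, slope_mz = 42.5 / 1400,
         coef_hydrophobicity = 0.1, coef_mobile_protons = -3.5,
         coef_glycan_mass = -0.003,
         optimum_noise_sd = 3, curve_sigma_mean = 12, curve_sigma_cv = 0.2,
         peak_score_log_mean = log(50), peak_score_log_sd = 0.9,
         detection_threshold = 10, multiplicative_score_noise_sd = 0.05)
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad))
    stop("unknown persona parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(p$slope_mz > 0, p$curve_sigma_mean > 0,
            p$detection_threshold >= 0)
  structure(p, class = "persona_params")
}

#' Per-channel persona assignment
#'
#' Byonic and the pGlyco peptide score follow the peptide-centric
#' archetype; the pGlyco glycan score, pGlyco total score and GlycoQuest
#' follow the glycan-centric one (the total score sits between the two in
#' reality; mapping it to the glycan archetype is a documented
#' simplification). Peak-score scales and detection thresholds are set per
#' channel so that scores live on each engine's native scale.
#'
#' @param peptide,glycan Archetype parameter overrides, passed as lists of
#'   persona fields applied to every channel of that archetype.
#' @return Named list of `persona_params`, one per score channel.
#' @export
channel_personas <- function(peptide = list(), glycan = list()) {
  pp <- function(...) do.call(persona_params,
                              c(list("peptide_centric"),
                                utils::modifyList(list(...), peptide)))
  gp <- function(...) do.call(persona_params,
                              c(list("glycan_centric"),
                                utils::modifyList(list(...), glycan)))
  list(
    byonic = pp(peak_score_log_mean = log(800), peak_score_log_sd = 0.9,
                detection_threshold = 100),
    pglyco_peptide = pp(peak_score_log_mean = log(70),
                        peak_score_log_sd = 0.9, detection_threshold = 2),
    pglyco_glycan = gp(peak_score_log_mean = log(50),
                       peak_score_log_sd = 0.9, detection_threshold = 2),
    pglyco_total = gp(peak_score_log_mean = log(40),
                      peak_score_log_sd = 0.8, detection_threshold = 3),
    glycoquest = gp(peak_score_log_mean = log(90), peak_score_log_sd = 0.8,
                    detection_threshold = 10)
  )
}

# Rough vertebrate proteome residue frequencies for random peptides.
.AA_BACKGROUND <- c(
  A = 7.0, R = 4.7, N = 3.6, D = 4.8, C = 2.3, Q = 4.8, E = 7.1, G = 6.6,
  H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.1, F = 3.7, P = 6.3, S = 8.3,
  T = 5.3, W = 1.2, Y = 2.7, V = 6.0
)

# Built-in glycan catalog: high-mannose Man5-Man9 plus complex bi/tri/
# tetra-antennary structures with 0..a sialic acids and 0-1 core fucose.
glycan_catalog <- function() {
  out <- lapply(5:9, function(h) sprintf("HexNAc(2)Hex(%d)", h))
  for (a in 2:4) for (s in 0:a) for (f in 0:1) {
    txt <- sprintf("HexNAc(%d)Hex(%d)", 2 + a, 3 + a)
    if (s > 0) txt <- paste0(txt, sprintf("NeuAc(%d)", s))
    if (f > 0) txt <- paste0(txt, sprintf("Fuc(%d)", f))
    out <- c(out, txt)
  }
  unlist(out)
}

#' Sample a synthetic glycopeptide cohort
#'
#' Draws tryptic-like peptides (length 7–25, background residue
#' frequencies, C-terminal K/R, one N-X-T sequon inserted), glycans from
#' the built-in high-mannose/complex catalog, and charges 2–4 weighted by
#' total mass (heavier species charge higher). A retention time is
#' assigned as a linear map of hydrophobicity plus noise, emulating the
#' hydrophobicity–retention correlation. Byte-identical under a fixed
#' seed.
#'
#' @param n Number of species.
#' @param seed RNG seed.
#' @return List of [glycopeptide_species()].
#' @export
sample_species <- function(n, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  catalog <- glycan_catalog()
  freqs <- .AA_BACKGROUND / sum(.AA_BACKGROUND)
  # internal residues: avoid K/R so peptides stay fully tryptic
  internal <- freqs[setdiff(names(freqs), c("K", "R"))]
  internal <- internal / sum(internal)
  lapply(seq_len(n), function(i) {
    len <- sample(7:25, 1)
    body <- sample(names(internal), len - 1L, replace = TRUE,
                   prob = internal)
    cterm <- sample(c("K", "R"), 1, prob = c(0.4, 0.6))
    # one N-X-T sequon at a random interior position
    pos <- sample(seq_len(max(1L, len - 3L)), 1)
    body[pos] <- "N"
    if (pos + 2L <= len - 1L) body[pos + 2L] <- "T"
    seqn <- paste0(paste(body, collapse = ""), cterm)
    glycan <- catalog[sample.int(length(catalog), 1)]
    mass <- peptide_mass(seqn) + glycan_mass(glycan)
    w <- if (mass < 2500) c(0.6, 0.3, 0.1)
         else if (mass < 3500) c(0.25, 0.55, 0.2)
         else c(0.05, 0.5, 0.45)
    z <- sample(2:4, 1, prob = w)
    sp <- glycopeptide_species(seqn, glycan, z)
    sp$retention_time <- max(2, 30 + 1.2 * hydrophobicity(seqn) +
                               stats::rnorm(1, 0, 5))
    sp$observed_mz <- theoretical_mz(sp)
    sp
  })
}

#' True optimal CE under a persona
#'
#' The generating model for the optimum: `mu = intercept + slope_mz * mz +
#' coef_hydro * hydrophobicity + coef_mobile * mobile_protons +
#' coef_glycan_mass * glycan_mass + N(0, optimum_noise_sd)`, clipped to
#' [5, ceiling] eV.
#'
#' @param features Feature data frame from [feature_table()] (or a single
#'   named feature vector).
#' @param persona A [persona_params()].
#' @param cal A [ce_calibration()] supplying the ceiling.
#' @return Numeric vector of true optima in eV (noise included unless
#'   `optimum_noise_sd` is 0; uses the current RNG stream).
#' @export
true_optimum <- function(features, persona, cal = ce_calibration()) {
  if (is.null(dim(features)))
    features <- as.data.frame(as.list(features))
  mu <- persona$intercept +
    persona$slope_mz * features$mz +
    persona$coef_hydrophobicity * features$hydrophobicity +
    persona$coef_mobile_protons * features$mobile_protons +
    persona$coef_glycan_mass * features$glycan_mass
  if (persona$optimum_noise_sd > 0)
    mu <- mu + stats::rnorm(nrow(features), 0, persona$optimum_noise_sd)
  pmin(cal$ceiling, pmax(5, mu))
}

#' Simulate the CE sweep experiment
#'
#' For every species, channel and sweep setting, draws the score
#' `A exp(-(CE - mu)^2 / (2 sigma^2)) * (1 + eps)` with multiplicative
#' Gaussian noise, emits a record only when it exceeds the channel's
#' detection threshold (score-driven missingness), and adds duplicate
#' identifications within a run with probability `p_dup`. Returns both
#' the records and the generating truth.
#'
#' @param species_list Cohort from [sample_species()].
#' @param grid A [sweep_grid()].
#' @param personas Named per-channel list from [channel_personas()].
#' @param cal A [ce_calibration()].
#' @param seed RNG seed.
#' @param p_dup Probability of a duplicate identification per record.
#' @return List: `records` (normalized record data frame), `truth` (data
#'   frame of per species/channel `true_mu`, `true_sigma`,
#'   `true_amplitude`), `features` ([feature_table()] of the cohort),
#'   `personas`, `grid`, `seed`.
#' @export
simulate_sweep <- function(species_list, grid = sweep_grid(),
                           personas = channel_personas(),
                           cal = ce_calibration(), seed = 1, p_dup = 0.05) {
  stopifnot(length(species_list) >= 1L, length(grid) >= 1L)
  set.seed(seed)
  feats <- feature_table(species_list)
  keys <- feats$species_key
  n <- length(species_list)
  scales <- as.numeric(grid)
  run_ids <- sprintf("run_%06.2fpct", scales)
  rts <- vapply(species_list, function(s) s$retention_time, numeric(1))
  seqs <- vapply(species_list, function(s) s$sequence, character(1))
  comps <- vapply(species_list, function(s)
    format_glycan_composition(s$glycan), character(1))
  zs <- vapply(species_list, function(s) s$charge, integer(1))
  # energy actually applied to species i at setting j
  ce <- outer(feats$mz, scales, function(m, s) applied_ce(m, s, cal))

  records <- vector("list", length(personas))
  truth <- vector("list", length(personas))
  for (ci in seq_along(personas)) {
    ch <- names(personas)[ci]
    p <- personas[[ci]]
    mu <- true_optimum(feats, p, cal)
    sigma <- p$curve_sigma_mean *
      exp(stats::rnorm(n, 0, p$curve_sigma_cv) - p$curve_sigma_cv^2 / 2)
    amp <- stats::rlnorm(n, p$peak_score_log_mean, p$peak_score_log_sd)
    clean <- amp * exp(-(ce - mu)^2 / (2 * sigma^2))
    eps <- matrix(stats::rnorm(length(clean), 0,
                               p$multiplicative_score_noise_sd),
                  nrow = n)
    score <- clean * (1 + eps)
    hit <- which(score > p$detection_threshold, arr.ind = TRUE)
    rec <- if (nrow(hit)) {
      data.frame(run_id = run_ids[hit[, 2]],
                 scale_pct = scales[hit[, 2]],
                 sequence = seqs[hit[, 1]],
                 glycan_composition = comps[hit[, 1]],
                 charge = zs[hit[, 1]],
                 channel = ch,
                 score = score[hit],
                 retention_time_min = round(rts[hit[, 1]] +
                                              stats::rnorm(nrow(hit), 0, 0.2), 3),
                 stringsAsFactors = FALSE)
    } else empty_records()
    if (nrow(rec) && p_dup > 0) {
      dup <- which(stats::runif(nrow(rec)) < p_dup)
      if (length(dup)) {
        extra <- rec[dup, , drop = FALSE]
        # an independent redraw of the same measurement, usually weaker
        extra$score <- extra$score *
          stats::runif(length(dup), 0.6, 1)
        extra$retention_time_min <- extra$retention_time_min +
          round(stats::runif(length(dup), 0.1, 1.5), 3)
        rec <- rbind(rec, extra)
      }
    }
    records[[ci]] <- rec
    truth[[ci]] <- data.frame(species_key = keys, channel = ch,
                              true_mu = mu, true_sigma = sigma,
                              true_amplitude = amp,
                              stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, records)
  records <- records[order(records$scale_pct, records$channel,
                           records$sequence, records$glycan_composition,
                           records$charge), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, truth = do.call(rbind, truth), features = feats,
       personas = personas, grid = grid, seed = seed)
}

#' Write simulated records as per-run report files
#'
#' One normalized TSV per sweep setting (including header-only files for
#' settings with no identifications) plus a `manifest.tsv` mapping run ids
#' to settings. Byte-identical under a fixed simulation seed.
#'
#' @param records Record data frame from [simulate_sweep()].
#' @param out_dir Output directory (created if needed).
#' @param grid The [sweep_grid()] used; settings absent from `records`
#'   still get an empty report.
#' @return Invisible character vector of file paths written.
#' @export
emit_reports <- function(records, out_dir, grid = sweep_grid()) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  scales <- as.numeric(grid)
  run_ids <- sprintf("run_%06.2fpct", scales)
  paths <- character(0)
  for (j in seq_along(scales)) {
    path <- file.path(out_dir, paste0(run_ids[j], ".tsv"))
    sub <- records[abs(records$scale_pct - scales[j]) < 1e-9, ,
                   drop = FALSE]
    write_report(sub, path)
    paths <- c(paths, path)
  }
  manifest <- file.path(out_dir, "manifest.tsv")
  utils::write.table(data.frame(run_id = run_ids, scale_pct = scales),
                     manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, manifest))
}

#' One-call synthetic cohort
#'
#' Convenience wrapper: samples a cohort, simulates the sweep, and returns
#' everything downstream stages need. Species sampling uses `seed`, the
#' sweep uses `seed + 1`.
#'
#' @param n Cohort size.
#' @param seed RNG seed.
#' @param personas Per-channel personas.
#' @param grid Sweep grid.
#' @param cal CE calibration.
#' @param p_dup Duplicate-record probability.
#' @return The [simulate_sweep()] list plus `species`.
#' @export
synthetic_cohort <- function(n = 300, seed = 1,
                             personas = channel_personas(),
                             grid = sweep_grid(), cal = ce_calibration(),
                             p_dup = 0.05) {
  species <- sample_species(n, seed)
  sim <- simulate_sweep(species, grid, personas, cal, seed = seed + 1L,
                        p_dup = p_dup)
  sim$species <- species
  sim
}
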
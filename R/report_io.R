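# Ingestion of CE-resolved search-engine reports into a normalized
# long-format score table. Vendor exports are abstracted as delimited-text
# dialects; the normalized TSV schema is the contract.

SCORE_CHANNELS <- c("byonic", "pglyco_peptide", "pglyco_glycan",
                    "pglyco_total", "glycoquest")

NORMALIZED_COLUMNS <- c("run_id", "scale_pct", "sequence",
                        "glycan_composition", "charge", "channel", "score",
                        "retention_time_min")

# Best-effort column maps for vendor-style delimited exports. Column names
# are tool-version dependent; override via `col_map`.
.DIALECT_MAPS <- list(
  byonic = c(sequence = "Peptide", glycan_composition = "Glycans",
             charge = "z", score = "Score",
             retention_time_min = "Scan Time"),
  pglyco = c(sequence = "Peptide", glycan_composition = "GlycanComposition",
             charge = "Charge", pglyco_peptide = "PepScore",
             pglyco_glycan = "GlyScore", pglyco_total = "TotalScore",
             retention_time_min = "RT"),
  glycoquest = c(peptide_mass = "PeptideMass",
                 glycan_composition = "GlycanComposition", charge = "Charge",
                 score = "Score", retention_time_min = "RT")
)

read_delim_checked <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path)
  tab <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE,
                                    check.names = FALSE),
                  error = function(e) stop("empty or unreadable report ",
                                           "file: ", path, call. = FALSE))
  tab
}

check_columns <- function(tab, required, path) {
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("report ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
}

# Validate glycan text; returns logical keep-mask, warns and counts skips.
valid_glycan_mask <- function(glycans, path) {
  ok <- vapply(glycans, function(g)
    !inherits(try(parse_glycan_composition(g), silent = TRUE), "try-error"),
    logical(1))
  if (any(!ok))
    warning(sum(!ok), " row(s) with unparseable glycan composition skipped",
            " in ", path, call. = FALSE)
  ok
}

#' Read one search-engine report
#'
#' Reads a per-run identification report into normalized records. Four
#' dialects are supported: `"normalized"` (the package's own TSV schema),
#' and delimited-text renderings of `"byonic"`, `"pglyco"` and
#' `"glycoquest"` exports. A pGlyco row yields three records (peptide,
#' glycan and total score channels). GlycoQuest reports carry no peptide
#' sequence, only a peptide mass; species are matched against
#' `species_list` by peptide mass (within `mass_tol` Da), glycan
#' composition and charge. Rows whose glycan composition does not parse are
#' skipped with a warning; the skip count is in attribute `"skipped"`.
#'
#' @param path Report file path (tab-delimited, UTF-8, header row).
#' @param dialect One of `"normalized"`, `"byonic"`, `"pglyco"`,
#'   `"glycoquest"`.
#' @param run_id,scale_pct Run label and sweep setting for the vendor
#'   dialects (the normalized dialect carries its own columns).
#' @param species_list List of [glycopeptide_species()] (glycoquest only).
#' @param col_map Named character vector overriding the dialect's default
#'   column map.
#' @param mass_tol Peptide-mass matching tolerance in Da (glycoquest).
#' @return Data frame of normalized records with attribute `"skipped"`.
#' @export
read_report <- function(path, dialect = c("normalized", "byonic", "pglyco",
                                          "glycoquest"),
                        run_id = NULL, scale_pct = NULL, species_list = NULL,
                        col_map = NULL, mass_tol = 0.02) {
  dialect <- match.arg(dialect)
  tab <- read_delim_checked(path)
  if (dialect == "normalized") {
    check_columns(tab, setdiff(NORMALIZED_COLUMNS, "retention_time_min"),
                  path)
    if (!"retention_time_min" %in% names(tab))
      tab$retention_time_min <- NA_real_
    if (nrow(tab)) {
      bad_channel <- setdiff(unique(tab$channel), SCORE_CHANNELS)
      if (length(bad_channel))
        stop("unknown score channel(s): ",
             paste(bad_channel, collapse = ", "))
    }
    keep <- if (nrow(tab)) valid_glycan_mask(tab$glycan_composition, path)
            else logical(0)
    out <- tab[keep, NORMALIZED_COLUMNS, drop = FALSE]
    rownames(out) <- NULL
    attr(out, "skipped") <- sum(!keep)
    return(out)
  }

  if (is.null(run_id) || is.null(scale_pct))
    stop("run_id and scale_pct are required for the ", dialect, " dialect")
  map <- .DIALECT_MAPS[[dialect]]
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  check_columns(tab, unname(map), path)
  skipped <- 0L

  if (dialect == "byonic") {
    keep <- valid_glycan_mask(tab[[map[["glycan_composition"]]]], path)
    skipped <- sum(!keep)
    tab <- tab[keep, , drop = FALSE]
    out <- data.frame(
      run_id = run_id, scale_pct = scale_pct,
      sequence = tab[[map[["sequence"]]]],
      glycan_composition = tab[[map[["glycan_composition"]]]],
      charge = as.integer(tab[[map[["charge"]]]]),
      channel = "byonic",
      score = as.numeric(tab[[map[["score"]]]]),
      retention_time_min = as.numeric(tab[[map[["retention_time_min"]]]]),
      stringsAsFactors = FALSE)
  } else if (dialect == "pglyco") {
    keep <- valid_glycan_mask(tab[[map[["glycan_composition"]]]], path)
    skipped <- sum(!keep)
    tab <- tab[keep, , drop = FALSE]
    channels <- c(pglyco_peptide = "pglyco_peptide",
                  pglyco_glycan = "pglyco_glycan",
                  pglyco_total = "pglyco_total")
    out <- do.call(rbind, lapply(names(channels), function(ch) {
      data.frame(
        run_id = run_id, scale_pct = scale_pct,
        sequence = tab[[map[["sequence"]]]],
        glycan_composition = tab[[map[["glycan_composition"]]]],
        charge = as.integer(tab[[map[["charge"]]]]),
        channel = ch,
        score = as.numeric(tab[[map[[ch]]]]),
        retention_time_min = as.numeric(tab[[map[["retention_time_min"]]]]),
        stringsAsFactors = FALSE)
    }))
  } else { # glycoquest: match peptide mass against the species list
    if (is.null(species_list))
      stop("species_list is required for the glycoquest dialect")
    keep <- valid_glycan_mask(tab[[map[["glycan_composition"]]]], path)
    skipped <- sum(!keep)
    tab <- tab[keep, , drop = FALSE]
    ref_mass <- vapply(species_list, function(s)
      peptide_mass(s$sequence, s$fixed_mods), numeric(1))
    ref_comp <- vapply(species_list, function(s)
      format_glycan_composition(s$glycan), character(1))
    ref_z <- vapply(species_list, function(s) s$charge, integer(1))
    rows <- lapply(seq_len(nrow(tab)), function(i) {
      comp_i <- format_glycan_composition(
        parse_glycan_composition(tab[[map[["glycan_composition"]]]][i]))
      hit <- which(abs(ref_mass - tab[[map[["peptide_mass"]]]][i]) <= mass_tol &
                     ref_comp == comp_i &
                     ref_z == as.integer(tab[[map[["charge"]]]][i]))
      if (!length(hit)) return(NULL)
      hit <- hit[which.min(abs(ref_mass[hit] -
                                 tab[[map[["peptide_mass"]]]][i]))]
      data.frame(
        run_id = run_id, scale_pct = scale_pct,
        sequence = species_list[[hit]]$sequence,
        glycan_composition = comp_i,
        charge = as.integer(tab[[map[["charge"]]]][i]),
        channel = "glycoquest",
        score = as.numeric(tab[[map[["score"]]]][i]),
        retention_time_min = as.numeric(tab[[map[["retention_time_min"]]]][i]),
        stringsAsFactors = FALSE)
    })
    unmatched <- sum(vapply(rows, is.null, logical(1)))
    if (unmatched)
      warning(unmatched, " glycoquest row(s) with no species-list match",
              " skipped in ", path, call. = FALSE)
    skipped <- skipped + unmatched
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- empty_records()
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

empty_records <- function() {
  data.frame(run_id = character(0), scale_pct = numeric(0),
             sequence = character(0), glycan_composition = character(0),
             charge = integer(0), channel = character(0), score = numeric(0),
             retention_time_min = numeric(0), stringsAsFactors = FALSE)
}

#' Write records to the normalized TSV schema
#'
#' @param records Normalized record data frame.
#' @param path Output path.
#' @export
write_report <- function(records, path) {
  utils::write.table(records[, NORMALIZED_COLUMNS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run manifest
#'
#' Tab-delimited file mapping `run_id` to `scale_pct` — the lab-specific
#' link between report files and sweep settings.
#'
#' @param path Manifest path.
#' @return Data frame with columns `run_id`, `scale_pct`.
#' @export
read_run_manifest <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(tab, c("run_id", "scale_pct"), path)
  tab
}

#' Keep the best identification per species, run and channel
#'
#' When a species was identified more than once in the same run (measured
#' several times at the same CE setting) the best-scoring match is kept.
#' Score ties are broken by earliest retention time, then input order.
#'
#' @param records Normalized record data frame.
#' @return Deduplicated `score_table` data frame (at most one record per
#'   species, run, channel).
#' @export
aggregate_best_per_run <- function(records) {
  if (!nrow(records)) {
    out <- records
    class(out) <- c("score_table", class(out))
    return(out)
  }
  key <- paste(records$sequence, records$glycan_composition, records$charge,
               records$run_id, records$channel, sep = "|")
  rt <- ifelse(is.na(records$retention_time_min), Inf,
               records$retention_time_min)
  ord <- order(key, -records$score, rt, seq_len(nrow(records)))
  out <- records[ord[!duplicated(key[ord])], , drop = FALSE]
  out <- out[order(out$channel, out$sequence, out$glycan_composition,
                   out$charge, out$scale_pct), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- NULL
  class(out) <- unique(c("score_table", class(out)))
  out
}
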
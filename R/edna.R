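#' Construct an ASV read-count table
#'
#' Container for a post-denoising amplicon sequence variant (ASV) table:
#' integer read counts over (ASV, sample) and per-ASV taxonomy with an
#' assignment confidence. This is the unit the detection-filtering chain
#' operates on; upstream read processing (denoising, chimera removal,
#' classifier training) is out of scope and assumed done.
#'
#' @param reads Integer matrix, ASVs in rows (rownames = ASV ids), samples
#'   in columns (colnames = sample ids). Non-negative.
#' @param taxonomy Data frame with columns `asv_id`, `class`, `order`,
#'   `family`, `genus`, `species`, `confidence` (percent, for the deepest
#'   assigned rank). Empty strings mark unassigned ranks.
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(reads, taxonomy) {
  reads <- as.matrix(reads)
  if (is.null(rownames(reads)) || is.null(colnames(reads)))
    stop("reads must have ASV rownames and sample colnames")
  if (any(reads < 0) || any(reads != round(reads)))
    stop("reads must be non-negative integers")
  storage.mode(reads) <- "integer"
  need <- c("asv_id", "class", "order", "family", "genus", "species",
            "confidence")
  missing <- setdiff(need, names(taxonomy))
  if (length(missing))
    stop("taxonomy missing column(s): ", paste(missing, collapse = ", "))
  taxonomy <- taxonomy[match(rownames(reads), taxonomy$asv_id), need,
                       drop = FALSE]
  if (any(is.na(taxonomy$asv_id)))
    stop("taxonomy missing rows for some ASVs in the read matrix")
  rownames(taxonomy) <- NULL
  for (nm in c("class", "order", "family", "genus", "species")) {
    taxonomy[[nm]] <- as.character(taxonomy[[nm]])
    taxonomy[[nm]][is.na(taxonomy[[nm]])] <- ""
  }
  taxonomy$confidence <- as.double(taxonomy$confidence)
  structure(list(reads = reads, taxonomy = taxonomy), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d ASVs x %d samples, %s reads\n",
              nrow(x$reads), ncol(x$reads),
              format(sum(as.double(x$reads)), big.mark = ",")))
  invisible(x)
}

#' Validate sample metadata against an ASV table
#'
#' Metadata columns: `sample_id`, `station_id`, `month`, `type` (one of
#' `sample`, `field_control`, `extraction_control`, `pcr_control`) and
#' `paired_control_id` — every water sample must reference exactly one
#' paired field control, the blank filtered alongside it.
#'
#' @param meta Sample metadata data frame.
#' @param table Optional [asv_table()]; when given, every read column must
#'   appear in the metadata.
#' @return `meta`, invisibly, with `type` normalised to character.
#' @export
validate_sample_metadata <- function(meta, table = NULL) {
  need <- c("sample_id", "station_id", "month", "type", "paired_control_id")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop("configuration error: sample metadata missing column(s): ",
         paste(missing, collapse = ", "))
  meta$type <- as.character(meta$type)
  bad_type <- setdiff(unique(meta$type),
                      c("sample", "field_control", "extraction_control",
                        "pcr_control"))
  if (length(bad_type))
    stop("unknown sample type(s): ", paste(bad_type, collapse = ", "))
  smp <- meta[meta$type == "sample", ]
  ctl_ids <- meta$sample_id[meta$type == "field_control"]
  unpaired <- smp$sample_id[is.na(smp$paired_control_id) |
                            !(smp$paired_control_id %in% ctl_ids)]
  if (length(unpaired))
    stop("samples without a paired field control: ",
         paste(unpaired, collapse = ", "))
  if (any(!nzchar(smp$station_id)) || any(!nzchar(as.character(smp$month))))
    stop("samples must carry non-empty station_id and month")
  if (!is.null(table)) {
    extra <- setdiff(colnames(table$reads), meta$sample_id)
    if (length(extra))
      stop("read columns absent from metadata: ", paste(extra, collapse = ", "))
  }
  invisible(meta)
}

step_log <- function(step, before, after) {
  data.frame(
    step = step,
    n_asvs = nrow(after$reads),
    n_samples = ncol(after$reads),
    total_reads = sum(as.double(after$reads)),
    reads_removed = sum(as.double(before$reads)) - sum(as.double(after$reads)),
    rows_dropped = nrow(before$reads) - nrow(after$reads),
    cells_zeroed = {
      # cells that went from positive to zero among surviving rows/columns
      keep_r <- intersect(rownames(before$reads), rownames(after$reads))
      keep_c <- intersect(colnames(before$reads), colnames(after$reads))
      sum(before$reads[keep_r, keep_c, drop = FALSE] > 0 &
          after$reads[keep_r, keep_c, drop = FALSE] == 0)
    },
    stringsAsFactors = FALSE)
}

#' Subtract paired negative controls
#'
#' For every water sample, any ASV with at least one read in its paired
#' field control is treated as contamination and zeroed in that sample —
#' the stringent per-sample blank subtraction used for metabarcoding
#' surveys with one control per sample. Control columns are then dropped
#' (optionally retained for a second subtraction pass later in the chain).
#'
#' @param table An [asv_table()].
#' @param meta Validated sample metadata (see [validate_sample_metadata()]).
#' @param drop_controls Drop all non-`sample` columns afterwards (default
#'   `TRUE`).
#' @return A filtered `asv_table` with a `step_log` attribute.
#' @export
subtract_controls <- function(table, meta, drop_controls = TRUE) {
  meta <- validate_sample_metadata(meta, table)
  before <- table
  reads <- table$reads
  smp <- meta[meta$type == "sample" & meta$sample_id %in% colnames(reads), ]
  for (k in seq_len(nrow(smp))) {
    cid <- smp$paired_control_id[k]
    if (!cid %in% colnames(reads)) next  # control column not sequenced
    hit <- reads[, cid] >= 1L
    reads[hit, smp$sample_id[k]] <- 0L
  }
  if (drop_controls) {
    keep <- colnames(reads) %in% meta$sample_id[meta$type == "sample"]
    reads <- reads[, keep, drop = FALSE]
  }
  out <- asv_table(reads, table$taxonomy)
  attr(out, "step_log") <- step_log("subtract_controls", before, out)
  out
}

#' Retain only ASVs assigned to the target class
#'
#' Drops every ASV whose class-level assignment is outside the target group
#' (for elasmobranch surveys, `"Elasmobranchii"`): teleosts, bacteria,
#' human reads and class-unassigned sequences, which cannot be confirmed
#' in-group, are all removed.
#'
#' @param table An [asv_table()].
#' @param target_class Class-level taxa to retain.
#' @return A filtered `asv_table` with a `step_log` attribute.
#' @export
filter_target_taxa <- function(table, target_class = "Elasmobranchii") {
  before <- table
  keep <- table$taxonomy$class %in% target_class
  out <- asv_table(table$reads[keep, , drop = FALSE],
                   table$taxonomy[keep, , drop = FALSE])
  attr(out, "step_log") <- step_log("filter_target_taxa", before, out)
  out
}

#' Remove singletons
#'
#' A singleton is a sequence with exactly one read in a sample; these are
#' overwhelmingly sequencing or index-hopping noise and are zeroed
#' per-cell, so a taxon can still survive through other samples.
#'
#' @param table An [asv_table()].
#' @return A filtered `asv_table` with a `step_log` attribute.
#' @export
drop_singletons <- function(table) {
  before <- table
  reads <- table$reads
  reads[reads == 1L] <- 0L
  out <- asv_table(reads, table$taxonomy)
  attr(out, "step_log") <- step_log("drop_singletons", before, out)
  out
}

#' Apply taxonomy assignment rules
#'
#' Drops ASVs not assigned to genus level or deeper at the classifier
#' confidence threshold, and ASVs whose species is on a known-contaminant
#' list (e.g. taxa handled in the same lab but impossible in the study
#' area). ASVs confidently assigned to genus but not species are retained
#' and flagged `genus_only`: they stand as genus-level records but are
#' excluded from species-level detection counts.
#'
#' @param table An [asv_table()].
#' @param min_confidence Assignment confidence threshold in percent
#'   (default 40, the classifier's "moderate" setting).
#' @param contaminants Character vector of contaminant species names.
#' @return A filtered `asv_table` whose taxonomy gains a logical
#'   `genus_only` column; `step_log` attribute attached.
#' @export
apply_taxonomy_rules <- function(table, min_confidence = 40,
                                 contaminants = character()) {
  before <- table
  tax <- table$taxonomy
  keep <- nzchar(tax$genus) & !is.na(tax$confidence) &
    tax$confidence >= min_confidence &
    !(tax$species %in% contaminants[nzchar(contaminants)])
  out <- asv_table(table$reads[keep, , drop = FALSE],
                   tax[keep, , drop = FALSE])
  out$taxonomy$genus_only <- !nzchar(out$taxonomy$species)
  attr(out, "step_log") <- step_log("apply_taxonomy_rules", before, out)
  out
}

#' Build the species detection matrix
#'
#' Any taxon with surviving reads after the filter chain is a positive
#' detection. Species-level detections are aggregated over ASVs and rolled
#' up to station x month through the sample metadata; genus-only flagged
#' ASVs are excluded from the species matrix (reported separately).
#'
#' @param table A filtered [asv_table()] (output of the filter chain).
#' @param meta Validated sample metadata.
#' @return An object of class `detection_matrix`: `by_sample` (long data
#'   frame `species`, `sample_id`, `station`, `month`, `reads` for every
#'   positive species x sample cell), `by_station_month` (distinct
#'   `species`, `station`, `month` rows), `species` (sorted detected
#'   species), and `genus_only` (genus-level records excluded from the
#'   species matrix).
#' @export
build_detections <- function(table, meta) {
  meta <- validate_sample_metadata(meta)
  tax <- table$taxonomy
  if (is.null(tax$genus_only)) tax$genus_only <- !nzchar(tax$species)
  sp_rows <- which(!tax$genus_only)
  smp_cols <- colnames(table$reads) %in% meta$sample_id[meta$type == "sample"]
  reads <- table$reads[sp_rows, smp_cols, drop = FALSE]
  by_sample <- data.frame(species = character(), sample_id = character(),
                          station = character(), month = character(),
                          reads = integer(), stringsAsFactors = FALSE)
  if (nrow(reads) && ncol(reads)) {
    agg <- rowsum(reads, group = tax$species[sp_rows])
    pos <- which(agg > 0, arr.ind = TRUE)
    if (nrow(pos)) {
      sid <- colnames(agg)[pos[, 2]]
      m <- meta[match(sid, meta$sample_id), ]
      by_sample <- data.frame(species = rownames(agg)[pos[, 1]],
                              sample_id = sid,
                              station = m$station_id,
                              month = as.character(m$month),
                              reads = agg[pos], stringsAsFactors = FALSE)
      by_sample <- by_sample[order(by_sample$species, by_sample$sample_id), ]
      rownames(by_sample) <- NULL
    }
  }
  by_station_month <- unique(by_sample[, c("species", "station", "month")])
  rownames(by_station_month) <- NULL
  genus_only <- tax[tax$genus_only, c("asv_id", "genus", "confidence"),
                    drop = FALSE]
  rownames(genus_only) <- NULL
  structure(list(by_sample = by_sample,
                 by_station_month = by_station_month,
                 species = sort(unique(by_sample$species)),
                 genus_only = genus_only),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat(sprintf(
    "detection_matrix: %d species, %d species x sample detections (%d at station x month)\n",
    length(x$species), nrow(x$by_sample), nrow(x$by_station_month)))
  if (nrow(x$genus_only))
    cat(sprintf("  + %d genus-only record(s) excluded from the species matrix\n",
                nrow(x$genus_only)))
  invisible(x)
}

#' Summarise a detection matrix
#'
#' Reports the headline survey numbers: discrete detections counted both as
#' species x sample positives and as species x station x month positives
#' (the two conventions in use), species richness, and the number and
#' percentage (1 d.p.) of water samples with at least one detection.
#'
#' @param dm A [build_detections()] result.
#' @param meta Validated sample metadata (supplies the water-sample
#'   denominator).
#' @return A list of summary statistics; `per_species_month` is a count
#'   table of detections by species and month.
#' @export
summarize_detections <- function(dm, meta) {
  meta <- validate_sample_metadata(meta)
  n_samples <- sum(meta$type == "sample")
  pos_samples <- unique(dm$by_sample$sample_id)
  per_species_month <- if (nrow(dm$by_sample))
    table(species = dm$by_sample$species, month = dm$by_sample$month)
  else table(character(), character())
  list(n_detections_species_sample = nrow(dm$by_sample),
       n_detections_station_month = nrow(dm$by_station_month),
       n_species = length(dm$species),
       n_samples = n_samples,
       n_samples_detected = length(pos_samples),
       pct_samples_detected = round(100 * length(pos_samples) /
                                      max(n_samples, 1L), 1),
       per_species_month = per_species_month)
}

#' Run the full detection-filtering chain
#'
#' Applies, in order: paired-control subtraction, target-class filtering,
#' singleton removal, and the taxonomy rules, then builds the detection
#' matrix. Per-step read/row attrition is logged. Extraction and PCR blanks
#' are not subtracted (only field controls are); instead they are screened
#' for target-class reads and reported.
#'
#' @inheritParams subtract_controls
#' @inheritParams filter_target_taxa
#' @inheritParams apply_taxonomy_rules
#' @param second_control_pass Also subtract controls a second time at the
#'   end of the chain (sensitivity switch; default `FALSE`, a single
#'   up-front pass).
#' @return A list: `table` (filtered [asv_table()]), `detections`
#'   ([build_detections()] result), `log` (attrition data frame, one row
#'   per step) and `blank_screen` (target reads found in extraction/PCR
#'   blanks).
#' @export
run_filter_chain <- function(table, meta, target_class = "Elasmobranchii",
                             min_confidence = 40, contaminants = character(),
                             second_control_pass = FALSE) {
  meta <- validate_sample_metadata(meta, table)

  blanks <- meta$sample_id[meta$type %in%
                             c("extraction_control", "pcr_control")]
  blanks <- intersect(blanks, colnames(table$reads))
  in_group <- table$taxonomy$class %in% target_class
  blank_reads <- if (length(blanks))
    colSums(table$reads[in_group, blanks, drop = FALSE]) else integer()
  blank_screen <- data.frame(sample_id = blanks,
                             target_reads = as.integer(blank_reads),
                             stringsAsFactors = FALSE)

  steps <- list()
  t1 <- subtract_controls(table, meta, drop_controls = !second_control_pass)
  steps[[1]] <- attr(t1, "step_log")
  t2 <- filter_target_taxa(t1, target_class)
  steps[[2]] <- attr(t2, "step_log")
  t3 <- drop_singletons(t2)
  steps[[3]] <- attr(t3, "step_log")
  t4 <- apply_taxonomy_rules(t3, min_confidence, contaminants)
  steps[[4]] <- attr(t4, "step_log")
  if (second_control_pass) {
    t4 <- subtract_controls(t4, meta, drop_controls = TRUE)
    lg <- attr(t4, "step_log"); lg$step <- "subtract_controls_2"
    steps[[5]] <- lg
  }
  list(table = t4,
       detections = build_detections(t4, meta),
       log = do.call(rbind, steps),
       blank_screen = blank_screen)
}

#' Per-sample species incidence from a detection matrix
#'
#' @param dm A [build_detections()] result.
#' @param meta Validated sample metadata; supplies the full sample set so
#'   detection-free samples appear as empty rows.
#' @return Logical incidence matrix, samples in rows, species in columns.
#' @export
detection_incidence <- function(dm, meta) {
  meta <- validate_sample_metadata(meta)
  samples <- meta$sample_id[meta$type == "sample"]
  species <- dm$species
  inc <- matrix(FALSE, length(samples), max(length(species), 0L),
                dimnames = list(samples, species))
  if (nrow(dm$by_sample))
    inc[cbind(match(dm$by_sample$sample_id, samples),
              match(dm$by_sample$species, species))] <- TRUE
  inc
}

#' Permutation species accumulation curve
#'
#' Sample-based accumulation: for each sample count `k`, the mean over
#' random sample orderings of the cumulative species richness of the first
#' `k` samples. The curve is monotone non-decreasing and ends at the total
#' observed richness; a plateau indicates the survey effort was sufficient
#' to capture the detectable richness.
#'
#' @param incidence Logical/0-1 matrix, samples in rows, species in
#'   columns (see [detection_incidence()]).
#' @param n_permutations Number of random orderings (default 200; ignored
#'   for `method = "exact"`).
#' @param seed RNG seed (ignored for `method = "exact"`).
#' @param method `"random"` averages over random sample orderings;
#'   `"exact"` evaluates the permutation mean in closed form — because the
#'   richness of the first `k` samples depends only on which `k` samples
#'   they are, the mean over all orderings is the hypergeometric
#'   `E[S(k)] = sum_sp (1 - C(n - m_sp, k) / C(n, k))` with `m_sp` the
#'   number of samples containing species `sp`.
#' @return Data frame with `k`, `mean_richness` and, for
#'   `method = "random"`, `sd_richness`.
#' @export
accumulation_curve <- function(incidence, n_permutations = 200, seed = 1L,
                               method = c("random", "exact")) {
  method <- match.arg(method)
  incidence <- incidence > 0
  n <- nrow(incidence)
  if (n < 1L) stop("need at least one sample")
  if (ncol(incidence) == 0L)             # no species observed: flat zero
    return(data.frame(k = seq_len(n), mean_richness = numeric(n),
                      sd_richness = numeric(n)))
  if (method == "exact") {
    m <- colSums(incidence)
    mean_rich <- vapply(seq_len(n), function(k) {
      sum(1 - exp(lchoose(n - m, k) - lchoose(n, k)))
    }, 0)
    return(data.frame(k = seq_len(n), mean_richness = mean_rich))
  }
  rich <- with_seed(seed, function() {
    vapply(seq_len(n_permutations), function(p) {
      ord <- sample.int(n)
      m <- incidence[ord, , drop = FALSE]
      seen <- apply(m, 2, cummax)
      if (n == 1L) seen <- matrix(seen, nrow = 1L)
      rowSums(seen)
    }, numeric(n))
  })
  rich <- matrix(rich, nrow = n)
  data.frame(k = seq_len(n),
             mean_richness = rowMeans(rich),
             sd_richness = apply(rich, 1, stats::sd))
}

#' Read / write ASV tables and sample metadata
#'
#' The on-disk ASV table is a TSV with `asv_id`, one integer column per
#' sample, then `class`, `order`, `family`, `genus`, `species`,
#' `confidence`. Metadata is a CSV typed as in
#' [validate_sample_metadata()].
#'
#' @param path File path.
#' @return [read_asv_table()] returns an [asv_table()];
#'   [read_sample_metadata()] a validated data frame.
#' @export
read_asv_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  tax_cols <- c("class", "order", "family", "genus", "species", "confidence")
  missing <- setdiff(c("asv_id", tax_cols), names(df))
  if (length(missing))
    stop("ASV table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  sample_cols <- setdiff(names(df), c("asv_id", tax_cols))
  reads <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(reads) <- df$asv_id
  asv_table(reads, cbind(asv_id = df$asv_id, df[, tax_cols]))
}

#' @rdname read_asv_table
#' @param table An [asv_table()] to write.
#' @export
write_asv_table <- function(table, path) {
  df <- data.frame(asv_id = rownames(table$reads),
                   table$reads,
                   table$taxonomy[, c("class", "order", "family", "genus",
                                      "species", "confidence")],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_asv_table
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_metadata(meta)
  meta
}
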
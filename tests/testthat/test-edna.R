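test_that("paired-control subtraction zeroes contaminated cells only", {
  tax <- tiny_taxonomy(c("A1", "A2"))
  tab <- tiny_asv_table(
    list(S1 = c(A1 = 100, A2 = 50), S1_C = c(A1 = 2)),
    tax)
  meta <- tiny_meta("S1")
  out <- subtract_controls(tab, meta)
  expect_equal(unname(out$reads["A1", "S1"]), 0L)   # 2 control reads kill it
  expect_equal(unname(out$reads["A2", "S1"]), 50L)  # absent from control
  expect_false("S1_C" %in% colnames(out$reads))

  # an all-zero control changes nothing beyond being dropped
  tab2 <- tiny_asv_table(list(S1 = c(A1 = 10, A2 = 3), S1_C = c()), tax)
  out2 <- subtract_controls(tab2, meta)
  expect_equal(out2$reads[, "S1"], tab2$reads[, "S1"])
})

test_that("subtraction demands a complete sample-control pairing", {
  tax <- tiny_taxonomy("A1")
  tab <- tiny_asv_table(list(S1 = c(A1 = 5), S1_C = c()), tax)
  meta <- tiny_meta("S1")
  meta$paired_control_id[meta$type == "sample"] <- "NOPE"
  expect_error(subtract_controls(tab, meta), "S1")
})

test_that("target-class filtering keeps elasmobranchs and drops the rest", {
  tax <- rbind(tiny_taxonomy("A1"),
               tiny_taxonomy("A2", class = "Actinopteri",
                             genus = "Clupea", species = "Clupea harengus"),
               tiny_taxonomy("A3", class = ""))
  tab <- tiny_asv_table(list(S1 = c(A1 = 5, A2 = 9, A3 = 4), S1_C = c()), tax)
  out <- filter_target_taxa(tab)
  expect_identical(rownames(out$reads), "A1")
  lg <- attr(out, "step_log")
  expect_equal(lg$rows_dropped, 2)
})

test_that("singleton cells are zeroed per cell, not per row", {
  tax <- tiny_taxonomy(c("A1", "A2"))
  tab <- tiny_asv_table(list(S1 = c(A1 = 1, A2 = 2),
                             S2 = c(A1 = 7, A2 = 1),
                             S1_C = c(), S2_C = c()), tax)
  out <- drop_singletons(tab)
  expect_equal(unname(out$reads["A1", c("S1", "S2")]), c(0L, 7L))
  expect_equal(unname(out$reads["A2", c("S1", "S2")]), c(2L, 0L))
  expect_equal(attr(out, "step_log")$cells_zeroed, 2)

  ones <- tiny_asv_table(list(S1 = c(A1 = 1, A2 = 1)), tiny_taxonomy(c("A1", "A2")))
  expect_true(all(drop_singletons(ones)$reads == 0L))
})

test_that("taxonomy rules enforce genus rank, confidence and contaminants", {
  tax <- rbind(
    tiny_taxonomy("A1"),                                  # full species, 90%
    tiny_taxonomy("A2", genus = "", species = ""),        # family level only
    tiny_taxonomy("A3", genus = "Raja", species = "", confidence = 45),
    tiny_taxonomy("A4", confidence = 20),                 # below threshold
    tiny_taxonomy("A5", genus = "Carcharhinus",
                  species = "Carcharhinus amblyrhynchos"))
  tab <- tiny_asv_table(list(S1 = c(A1 = 5, A2 = 5, A3 = 5, A4 = 5, A5 = 5)),
                        tax)
  out <- apply_taxonomy_rules(tab, min_confidence = 40,
                              contaminants = "Carcharhinus amblyrhynchos")
  expect_setequal(rownames(out$reads), c("A1", "A3"))
  expect_equal(out$taxonomy$genus_only[out$taxonomy$asv_id == "A3"], TRUE)
  expect_equal(out$taxonomy$genus_only[out$taxonomy$asv_id == "A1"], FALSE)
})

test_that("detections aggregate to station x month and exclude genus-only rows", {
  tax <- rbind(tiny_taxonomy("A1"),
               tiny_taxonomy("A3", genus = "Raja", species = "",
                             confidence = 45))
  tab <- tiny_asv_table(list(S1 = c(A1 = 5, A3 = 8), S1_C = c()), tax)
  meta <- tiny_meta("S1", stations = "PO", months = "Jun")
  filt <- apply_taxonomy_rules(tab)
  dm <- build_detections(filt, meta)
  expect_equal(dm$by_sample$species, "Scyliorhinus canicula")
  expect_equal(dm$by_sample$station, "PO")
  expect_equal(dm$by_sample$month, "Jun")
  expect_equal(nrow(dm$genus_only), 1)
  expect_false("Raja" %in% dm$species)

  empty <- tiny_asv_table(list(S1 = c(A1 = 0), S1_C = c()),
                          tiny_taxonomy("A1"))
  dm0 <- build_detections(empty, meta)
  expect_equal(nrow(dm0$by_sample), 0)
  expect_equal(length(dm0$species), 0)
})

test_that("summary arithmetic reports detection proportions to 1 d.p.", {
  # 240 water samples, an elasmobranch surviving in exactly 105 of them
  n <- 240
  samples <- sprintf("S%03d", seq_len(n))
  meta <- tiny_meta(samples, stations = sprintf("ST%02d", rep(1:10, 24)),
                    months = rep(month.abb, each = 20))
  counts <- c(rep(5L, 105), rep(0L, n - 105))
  reads <- lapply(seq_len(n), function(i) c(A1 = counts[i]))
  names(reads) <- samples
  reads <- c(reads, setNames(lapply(samples, function(s) c()),
                             paste0(samples, "_C")))
  tab <- tiny_asv_table(reads, tiny_taxonomy("A1"))
  res <- run_filter_chain(tab, meta)
  s <- summarize_detections(res$detections, meta)
  expect_equal(s$n_samples, 240)
  expect_equal(s$n_samples_detected, 105)
  expect_equal(s$pct_samples_detected, 43.8)
  expect_equal(s$n_detections_species_sample, 105)

  # degenerate ends: none and all
  s0 <- summarize_detections(build_detections(
    tiny_asv_table(list(S1 = c(A1 = 0), S1_C = c()), tiny_taxonomy("A1")),
    tiny_meta("S1")), tiny_meta("S1"))
  expect_equal(s0$pct_samples_detected, 0)
  s1 <- summarize_detections(build_detections(
    tiny_asv_table(list(S1 = c(A1 = 4), S1_C = c()), tiny_taxonomy("A1")),
    tiny_meta("S1")), tiny_meta("S1"))
  expect_equal(s1$pct_samples_detected, 100)
})

test_that("the filter chain never increases reads and logs each step", {
  sv <- make_survey(seed = 17)
  res <- run_filter_chain(sv$table, sv$meta,
                          contaminants = sv$truth$contaminant_species)
  expect_identical(res$log$step,
                   c("subtract_controls", "filter_target_taxa",
                     "drop_singletons", "apply_taxonomy_rules"))
  expect_true(all(diff(res$log$total_reads) <= 0))
  expect_true(all(res$log$reads_removed >= 0))
  # per-cell monotonicity against the raw table
  raw <- sv$table$reads[rownames(res$table$reads),
                        colnames(res$table$reads)]
  expect_true(all(res$table$reads <= raw))
})

test_that("the chain recovers planted truth and honours the bookkeeping", {
  clean <- make_survey(leakage_rate = 0, singleton_rate = 0, seed = 23)
  res <- run_filter_chain(clean$table, clean$meta,
                          contaminants = clean$truth$contaminant_species)
  got <- res$detections$by_sample[, c("species", "sample_id")]
  want <- clean$truth$planted[, c("species", "sample_id")]
  expect_setequal(paste(got$species, got$sample_id),
                  paste(want$species, want$sample_id))

  noisy <- make_survey(leakage_rate = 0.3, singleton_rate = 0.05, seed = 29)
  resn <- run_filter_chain(noisy$table, noisy$meta,
                           contaminants = noisy$truth$contaminant_species)
  lg <- resn$log
  expect_equal(lg$cells_zeroed[lg$step == "subtract_controls"],
               unname(noisy$truth$expected_cells_zeroed["subtract_controls"]))
  expect_equal(lg$cells_zeroed[lg$step == "drop_singletons"],
               nrow(noisy$truth$singleton_events))
  gotn <- resn$detections$by_sample
  expect_setequal(paste(gotn$species, gotn$sample_id),
                  paste(noisy$truth$expected$species,
                        noisy$truth$expected$sample_id))
})

test_that("extraction and PCR blanks are screened, not subtracted", {
  sv <- make_survey(seed = 5)
  res <- run_filter_chain(sv$table, sv$meta,
                          contaminants = sv$truth$contaminant_species)
  expect_setequal(res$blank_screen$sample_id,
                  c("EXT_BLANK_1", "EXT_BLANK_2", "PCR_BLANK_1",
                    "PCR_BLANK_2"))
  expect_true(all(res$blank_screen$target_reads >= 0))
})

test_that("a second control-subtraction pass is available and idempotent here", {
  sv <- make_survey(seed = 11)
  once <- run_filter_chain(sv$table, sv$meta,
                           contaminants = sv$truth$contaminant_species)
  twice <- run_filter_chain(sv$table, sv$meta,
                            contaminants = sv$truth$contaminant_species,
                            second_control_pass = TRUE)
  expect_equal(nrow(twice$log), 5)
  # later steps cannot resurrect reads, so the second pass removes nothing new
  expect_setequal(paste(twice$detections$by_sample$species,
                        twice$detections$by_sample$sample_id),
                  paste(once$detections$by_sample$species,
                        once$detections$by_sample$sample_id))
})

test_that("accumulation curves are monotone and end at total richness", {
  sv <- make_survey(seed = 13)
  res <- run_filter_chain(sv$table, sv$meta,
                          contaminants = sv$truth$contaminant_species)
  inc <- detection_incidence(res$detections, sv$meta)
  acc <- accumulation_curve(inc, n_permutations = 60, seed = 2)
  expect_true(all(diff(acc$mean_richness) >= -1e-12))
  expect_equal(acc$mean_richness[nrow(acc)], length(res$detections$species))

  flat <- matrix(TRUE, 5, 1, dimnames = list(paste0("S", 1:5), "sp"))
  accf <- accumulation_curve(flat, n_permutations = 10, seed = 1)
  expect_equal(accf$mean_richness, rep(1, 5))
})

test_that("accumulation means match exhaustive order enumeration", {
  # two disjoint single-species samples: E[S(1)] = 1, E[S(2)] = 2
  inc <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2,
                dimnames = list(c("S1", "S2"), c("A", "B")))
  ex <- accumulation_curve(inc, method = "exact")
  expect_equal(ex$mean_richness, c(1, 2))

  # three samples: brute-force average over all 3! orderings
  inc3 <- matrix(c(TRUE, FALSE, TRUE,
                   FALSE, TRUE, TRUE,
                   FALSE, FALSE, TRUE), 3, 3,
                 dimnames = list(paste0("S", 1:3), c("A", "B", "C")))
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  brute <- rowMeans(vapply(perms, function(p) {
    m <- inc3[p, , drop = FALSE]
    vapply(1:3, function(k) sum(colSums(m[1:k, , drop = FALSE]) > 0), 0)
  }, numeric(3)))
  ex3 <- accumulation_curve(inc3, method = "exact")
  expect_equal(ex3$mean_richness, brute)
  # the permutation estimate converges to the same curve
  mc3 <- accumulation_curve(inc3, n_permutations = 4000, seed = 9)
  expect_equal(mc3$mean_richness, brute, tolerance = 0.05)
})

test_that("exact accumulation agrees with vegan's analytic rarefaction", {
  skip_if_not_installed("vegan")
  set.seed(4)
  inc <- matrix(runif(60) < 0.3, 10, 6,
                dimnames = list(paste0("S", 1:10), paste0("sp", 1:6)))
  ex <- accumulation_curve(inc, method = "exact")
  ref <- vegan::specaccum(inc * 1L, method = "exact")
  expect_equal(ex$mean_richness, as.numeric(ref$richness), tolerance = 1e-8)
})

test_that("ASV tables and metadata round-trip through TSV/CSV", {
  sv <- make_survey(n_stations = 3, n_months = 2, seed = 31)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_asv_table(sv$table, tsv)
  back <- read_asv_table(tsv)
  expect_identical(back$reads, sv$table$reads)
  expect_equal(back$taxonomy$species, sv$table$taxonomy$species)
  expect_equal(back$taxonomy$confidence, sv$table$taxonomy$confidence,
               tolerance = 1e-9)

  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(sv$meta, csv, row.names = FALSE)
  meta <- read_sample_metadata(csv)
  expect_equal(meta$sample_id, sv$meta$sample_id)
})
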
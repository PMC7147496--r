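# packaged synthetic study designs ("smoke" for fast checks, "full" for the
# planted-recovery experiment)

#' Build a synthetic study with planted ground truth
#'
#' The "full" preset emulates the mining experiment at desk scale: 200
#' background ESTs, 20 planted hairpins of which 15 satisfy all four homolog
#' criteria (stem mismatches 0--3, precursor lengths spanning roughly
#' 75--170 nt) and 5 each violate exactly one criterion, plus 8 transcripts
#' carrying 20 planted target sites with profiles on both sides of the
#' expectation and mismatch cutoffs. The "smoke" preset is a reduced copy
#' for fast tests (30 background ESTs, 4 hairpins, 6 target sites).
#'
#' @param preset "smoke" or "full"
#' @param seed master RNG seed (default 42); every random choice derives
#'   from it
#' @param params a [pipeline_config()] describing the thresholds the
#'   engineered hairpins must pass or fail
#' @return list with `refs`, `ests`, `transcripts`, `truth` (manifest with
#'   `planted_hairpins`, `planted_targets`, `seed`, `preset`)
#' @export
synth_preset <- function(preset = c("smoke", "full"), seed = 42L,
                         params = pipeline_config()) {
  preset <- match.arg(preset)
  set.seed(seed)
  n_hairpin <- if (preset == "full") 15L else 3L
  n_background <- if (preset == "full") 200L else 30L
  n_tx <- if (preset == "full") 8L else 2L

  # compliant hairpin designs: vary mature length, stem mismatches, stem
  # extension and loop to span precursor lengths like those of real
  # pre-miRNAs (roughly 75-170 nt)
  mlen <- rep(c(21L, 20L, 19L), length.out = n_hairpin)
  mm <- rep(c(0L, 1L, 2L, 3L, 0L), length.out = n_hairpin)
  ext <- rep(c(10L, 14L, 18L, 24L, 30L), length.out = n_hairpin)
  tails <- rep(c(5L, 10L, 16L, 22L, 28L), length.out = n_hairpin)
  loops <- rep(c(6L, 9L, 12L), length.out = n_hairpin)

  matures <- vapply(mlen, function(L) rand_seq(L, gc = 50), character(1))
  violation_reasons <- c("star_mismatches_gt5", "mfei_lt_threshold",
                         "no_stem_loop", "mature_spans_loop",
                         "length_out_of_range")
  if (preset == "smoke") violation_reasons <- "star_mismatches_gt5"
  viol_matures <- vapply(violation_reasons, function(r) {
    switch(r,
           mfei_lt_threshold = rand_seq(21L, alphabet = c("A", "T")),
           length_out_of_range = rand_seq(22L, gc = 55),
           rand_seq(21L, gc = 55))
  }, character(1))

  planted <- list()
  for (i in seq_len(n_hairpin)) {
    build <- local({
      i <- i
      function() plant_hairpin(matures[i], stem_mismatches = mm[i],
                               loop_len = loops[i], ext_stem = ext[i],
                               tail_len = tails[i])
    })
    planted[[length(planted) + 1L]] <- list(
      mirna_id = sprintf("syn-miR%03d", 200L + i), mature = matures[i],
      hairpin = build(), rebuild = build,
      strand = if (i %% 4L == 0L) "-" else "+", reason = "")
  }
  for (j in seq_along(violation_reasons)) {
    build <- local({
      j <- j
      function() plant_violator(violation_reasons[j], viol_matures[j],
                                params = params)
    })
    planted[[length(planted) + 1L]] <- list(
      mirna_id = sprintf("syn-miR%03d", 300L + j), mature = viol_matures[j],
      hairpin = build(), rebuild = build, strand = "+",
      reason = violation_reasons[j])
  }

  planted_refs <- data.frame(
    id = vapply(planted, `[[`, character(1), "mirna_id"),
    species_prefix = "syn",
    family = parse_mirna_family(vapply(planted, `[[`, character(1),
                                       "mirna_id"))$family,
    seq = vapply(planted, `[[`, character(1), "mature"),
    stringsAsFactors = FALSE)
  decoys <- make_reference_set(if (preset == "full") 10L else 4L,
                               seed = seed + 1L)
  refs <- rbind(planted_refs, decoys)

  col <- make_est_collection(n_background, planted, refs,
                             seed = seed + 2L,
                             orf_aa_threshold = params$orf_aa_threshold,
                             verify_params = params)

  # target-site profiles; each is a function of the miRNA length
  prof <- function(L, ...) {
    p <- rep("match", L)
    mods <- list(...)
    for (m in mods) p[m$at] <- m$state
    p
  }
  mod <- function(at, state) list(at = at, state = state)
  site_designs <- list(
    list(),                                              # perfect, exp 0
    list(mod(15, "wobble")),                             # exp 0.5
    list(mod(5, "wobble")),                              # seed wobble, exp 1
    list(mod(10, "mismatch")),                           # central, exp 2, Translation
    list(mod(11, "wobble")),                             # central, exp 1, Translation
    list(mod(5, "mismatch")),                            # seed mm, exp 2
    list(mod(15, "mismatch"), mod(18, "mismatch")),      # exp 2
    list(mod(3, "mismatch"), mod(16, "wobble")),         # exp 2.5
    list(mod(6, "mismatch"), mod(15, "mismatch")),       # exp 3
    list(mod(15, "wobble"), mod(17, "wobble")),          # exp 1
    list(mod(4, "wobble"), mod(16, "mismatch")),         # exp 2
    list(mod(2, "mismatch"), mod(19, "wobble")),         # exp 2.5
    list(mod(14, "mismatch"), mod(16, "mismatch"),
         mod(18, "mismatch")),                           # 3 mm states: excluded
    list(mod(4, "mismatch"), mod(8, "mismatch")),        # exp 4: excluded
    list(mod(15, "mismatch"), mod(17, "wobble"),
         mod(19, "wobble")),                             # exp 2.5
    list(mod(7, "wobble"), mod(15, "wobble")),           # exp 1.5
    list(mod(12, "mismatch")),                           # seed mm, exp 2
    list(mod(16, "mismatch"), mod(18, "wobble")),        # exp 1.5
    list(mod(3, "wobble"), mod(11, "mismatch")),         # exp 3, Translation
    list(mod(20, "wobble"))                              # exp 0.5
  )
  n_sites <- if (preset == "full") 20L else 6L
  site_designs <- site_designs[seq_len(n_sites)]
  # wobble states need a G or T at the modified miRNA position; draw site
  # miRNAs from the compliant planted matures and re-draw bases as needed
  site_mirnas <- planted_refs[rep(seq_len(n_hairpin),
                                  length.out = n_sites), ]
  sites <- vector("list", n_sites)
  for (k in seq_len(n_sites)) {
    q <- strsplit(site_mirnas$seq[k], "", fixed = TRUE)[[1]]
    p <- rep("match", length(q))
    for (m in site_designs[[k]]) {
      at <- m$at
      if (at > length(q)) at <- length(q) - 1L
      if (m$state == "wobble" && !(q[at] %in% c("G", "T"))) {
        q[at] <- sample(c("G", "T"), 1L)  # make the wobble realizable
      }
      p[at] <- m$state
    }
    # one scan identity per site (variant suffix keeps the family parseable)
    sites[[k]] <- list(mirna_id = paste0(site_mirnas$id[k], ".", k),
                       mirna_seq = paste(q, collapse = ""), profile = p)
  }
  tg <- plant_target_sites(n_tx, sites,
                           tx_length_range = if (preset == "full")
                             c(1000L, 1800L) else c(500L, 800L),
                           seed = seed + 3L,
                           scoring = params$duplex_scoring)
  # the site miRNA may differ from the planted mature where a wobble was
  # made realizable; record the scanned sequence in the manifest
  tg$truth$planted_targets$mirna_seq <-
    vapply(sites, function(s) s$mirna_seq, character(1))
  tg$truth$planted_targets$qualifies <-
    tg$truth$planted_targets$expected_expectation <= params$expectation_max &
    tg$truth$planted_targets$n_mismatch_states <= params$target_max_mismatches

  truth <- list(planted_hairpins = col$truth$planted_hairpins,
                planted_targets = tg$truth$planted_targets,
                seed = seed, preset = preset)
  list(refs = refs, ests = col$ests, transcripts = tg$transcripts,
       truth = truth)
}
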
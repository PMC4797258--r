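# Deconvolution experiment planning and plate-reader scoring: choose the
# nearest marker per candidate variant, size the transductant sample,
# warn about co-interval variant pairs, classify re-screen wells, and call
# the causative mutation.

#' Transductants needed to see at least one co-replacement
#'
#' Smallest `n` with `1 - (1 - freq)^n >= confidence`: the number of
#' transductants to pick so that, with the stated confidence, at least one
#' carries the donor (wild-type) sequence at the linked locus.
#'
#' @param freq Co-transduction frequency in `(0, 1]`.
#' @param confidence Target probability in `(0, 1)`.
#' @return Positive integer.
#' @examples
#' n_transductants_for_confidence(0.35, 0.99)  # 11
#' @export
n_transductants_for_confidence <- function(freq, confidence = 0.99) {
  if (any(confidence <= 0) || any(confidence >= 1)) {
    stop("confidence must be in (0, 1)")
  }
  if (any(freq <= 0)) {
    stop("freq must be positive: a locus with zero co-transduction ",
         "frequency cannot be covered by any number of transductants")
  }
  if (any(freq > 1)) stop("freq must be at most 1")
  n <- ceiling(log(1 - confidence) / log1p(-pmin(freq, 1 - 1e-15)))
  pmax(1, ifelse(freq >= 1, 1, n))
}

#' Build a transduction deconvolution plan for a set of candidate variants
#'
#' For each variant: the nearest marker of the library, the distance under
#' that marker's reference convention, the predicted co-transduction
#' frequency, and the recommended number of transductants to pick
#' (`min(max_picks, n needed for the confidence level)`). Variants sharing
#' a nearest marker are cross-annotated with their pairwise separation
#' probability: a revertant for one may still carry the other. A variant
#' with frequency 0 (beyond the transducing segment) is flagged
#' `uncoverable`, never dropped. When a variant's two nearest markers lie
#' within `tie_window_bp` of each other in distance, the runner-up is
#' recorded as an alternative marker.
#'
#' @param variants data.frame from [load_variants()] (needs `variant_id`,
#'   `pos_bp`).
#' @param library A [marker_library()].
#' @param model A [linkage_model()].
#' @param confidence Per-variant probability that at least one picked
#'   transductant carries the replacement (default 0.99).
#' @param max_picks Cap on transductants per plate (default 22).
#' @param tie_window_bp Distance window for reporting an alternative,
#'   nearly-equidistant marker (default 1,000 bp).
#' @return data.frame of class `transduction_plan` with columns
#'   `variant_id`, `marker_allele`, `distance_bp`, `predicted_freq`,
#'   `freq_percent`, `n_transductants`, `capped`, `uncoverable`,
#'   `alt_marker`, `warnings` (semicolon-joined co-interval notes).
#' @export
build_plan <- function(variants, library, model = linkage_model(),
                       confidence = 0.99, max_picks = 22L,
                       tie_window_bp = 1000) {
  stopifnot(inherits(library, "marker_library"))
  if (!nrow(variants)) stop("no variants to plan for")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  if (max_picks < 1) stop("max_picks must be at least 1")
  n <- nrow(variants)
  marker <- character(n); dist <- numeric(n); alt <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    nm <- nearest_markers(variants$pos_bp[i], library, k = 2L)
    marker[i] <- nm$allele_id[1L]
    dist[i] <- nm$distance_bp[1L]
    if (nrow(nm) > 1L && nm$distance_bp[2L] - nm$distance_bp[1L] <= tie_window_bp) {
      alt[i] <- nm$allele_id[2L]
    }
  }
  freq <- wu_frequency(dist, model)
  uncoverable <- freq == 0
  n_needed <- rep(NA_real_, n)
  n_needed[!uncoverable] <- n_transductants_for_confidence(freq[!uncoverable],
                                                           confidence)
  picks <- ifelse(uncoverable, max_picks, pmin(max_picks, n_needed))
  capped <- uncoverable | n_needed > max_picks
  warnings <- character(n)
  for (i in seq_len(n)) {
    shared <- setdiff(which(marker == marker[i]), i)
    notes <- vapply(shared, function(j) {
      dn <- min(dist[i], dist[j]); df <- max(dist[i], dist[j])
      sep <- separation_probability(dn, df, model)
      sprintf("shares %s with %s (separation p=%.3f)", marker[i],
              variants$variant_id[j], sep)
    }, "")
    warnings[i] <- paste(notes, collapse = "; ")
  }
  out <- data.frame(
    variant_id = as.character(variants$variant_id),
    marker_allele = marker,
    distance_bp = round_half_up(dist),
    predicted_freq = freq,
    freq_percent = round_half_up(100 * freq),
    n_transductants = as.integer(picks),
    capped = capped,
    uncoverable = uncoverable,
    alt_marker = alt,
    warnings = warnings,
    stringsAsFactors = FALSE
  )
  class(out) <- c("transduction_plan", class(out))
  out
}

#' Write a transduction plan to TSV
#'
#' @param plan A [build_plan()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  cols <- c("variant_id", "marker_allele", "distance_bp", "predicted_freq",
            "freq_percent", "n_transductants", "warnings")
  write_tsv(format_num_df(as.data.frame(plan)[cols]), path)
}

#' Read a transduction plan written by [write_plan()]
#'
#' @param path Path to the plan TSV.
#' @return data.frame with at least `variant_id`, `marker_allele`,
#'   `predicted_freq`, `n_transductants`.
#' @export
load_plan <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  needed <- c("variant_id", "marker_allele", "predicted_freq")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("plan ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab
}

## ---- plate scoring ----------------------------------------------------

#' Read plate-reader measurements from TSV
#'
#' Expected columns: `well_id`, `group` (marker allele, or the reserved
#' control labels `WT_REF` / `MUT_REF`), `fluorescence`, `od600`.
#'
#' @param path Path to the plate TSV.
#' @return data.frame with the four columns plus `relative_fluorescence`
#'   (fluorescence per OD600 unit).
#' @export
load_plate <- function(path) {
  if (!file.exists(path)) stop("plate file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  needed <- c("well_id", "group", "fluorescence", "od600")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("plate ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(tab$od600 <= 0)) {
    stop("od600 must be positive; offending well: ",
         tab$well_id[tab$od600 <= 0][1L])
  }
  tab$relative_fluorescence <- tab$fluorescence / tab$od600
  tab
}

#' Summarise a reference group's relative fluorescence
#'
#' @param relative_fluorescence Numeric vector of fluorescence-per-OD600
#'   readings for a control group.
#' @return List with `log_mean` and `log_sd` of the log readings.
#' @export
reference_summary <- function(relative_fluorescence) {
  x <- relative_fluorescence
  if (any(x <= 0)) stop("relative fluorescence must be positive")
  lx <- log(x)
  list(log_mean = mean(lx), log_sd = if (length(lx) > 1L) stats::sd(lx) else 0)
}

#' Classify re-screen wells as reverted, mutant-like, or intermediate
#'
#' A well's log relative fluorescence is compared with the wild-type and
#' un-transduced-mutant reference means. It is called `reverted` when it
#' is closer to the wild-type mean by a margin of at least `g` pooled
#' standard deviations, `mutant-like` when closer to the mutant mean by
#' the same margin, and `intermediate` otherwise. References with zero
#' dispersion degrade (with a warning) to a plain nearest-mean rule.
#'
#' @param wells Plate data.frame ([load_plate()]), already restricted to
#'   the wells to classify.
#' @param wt_reference,mutant_reference [reference_summary()] objects for
#'   the wild-type and mutant controls.
#' @param g Margin in pooled standard deviations (default 1).
#' @return Character vector of labels, one per well, in
#'   `{reverted, mutant-like, intermediate}`.
#' @export
classify_wells <- function(wells, wt_reference, mutant_reference, g = 1) {
  if (any(wells$od600 <= 0)) {
    stop("od600 must be positive; offending well: ",
         wells$well_id[wells$od600 <= 0][1L])
  }
  lx <- log(wells$fluorescence / wells$od600)
  classify_log_rf(lx, wt_reference, mutant_reference, g)
}

# Core classification rule on log relative fluorescence values.
classify_log_rf <- function(lx, wt_reference, mutant_reference, g = 1) {
  pooled <- sqrt((wt_reference$log_sd^2 + mutant_reference$log_sd^2) / 2)
  if (pooled == 0) {
    warning("degenerate references (zero dispersion); using nearest-mean rule")
  }
  margin <- g * pooled
  d_wt <- abs(lx - wt_reference$log_mean)
  d_mut <- abs(lx - mutant_reference$log_mean)
  ifelse(d_mut - d_wt >= margin & d_mut > d_wt, "reverted",
         ifelse(d_wt - d_mut >= margin & d_wt > d_mut, "mutant-like",
                "intermediate"))
}

#' Call the causative variant from per-group well labels
#'
#' A transduction group (one marker, hence one planned variant) qualifies
#' as causative when at least `m` of its wells reverted the screened
#' phenotype. Exactly one qualifying group gives a `full` call for its
#' variant. No qualifying group but exactly one group with at least `m`
#' `intermediate` wells gives a `partial` call (replacement only partially
#' restored the wild-type phenotype, as when a second uncalled mutation
#' also contributes). Several qualifying groups give `ambiguous`; none
#' give `none`.
#'
#' @param labels data.frame with columns `group` and `label` (from
#'   [classify_wells()]), control groups excluded.
#' @param plan A [build_plan()] result covering every group in `labels`.
#' @param m Minimum revertant wells for a causative call (default 2).
#' @param mutant_id Identifier of the mutant strain being deconvolved.
#' @return List of class `deconvolution_call`: `mutant_id`,
#'   `causative_variant_id` (or `NA`), `call` in
#'   `{full, partial, none, ambiguous}`, and `tallies`, a per-group
#'   data.frame of reverted / intermediate / mutant-like counts.
#' @export
call_causative <- function(labels, plan, m = 2L, mutant_id = "mutant") {
  if (m < 1) stop("m must be at least 1")
  groups <- unique(labels$group)
  unknown <- setdiff(groups, plan$marker_allele)
  if (length(unknown)) {
    stop("group(s) absent from plan: ", paste(unknown, collapse = ", "))
  }
  tallies <- do.call(rbind, lapply(groups, function(gr) {
    lab <- labels$label[labels$group == gr]
    data.frame(group = gr,
               variant_id = plan$variant_id[match(gr, plan$marker_allele)],
               n_wells = length(lab),
               reverted = sum(lab == "reverted"),
               intermediate = sum(lab == "intermediate"),
               mutant_like = sum(lab == "mutant-like"),
               stringsAsFactors = FALSE)
  }))
  qualifying <- tallies$group[tallies$reverted >= m]
  partials <- tallies$group[tallies$reverted < m & tallies$intermediate >= m]
  if (length(qualifying) == 1L) {
    call <- "full"
    causative <- tallies$variant_id[tallies$group == qualifying]
  } else if (length(qualifying) > 1L) {
    call <- "ambiguous"
    causative <- NA_character_
  } else if (length(partials) == 1L) {
    call <- "partial"
    causative <- tallies$variant_id[tallies$group == partials]
  } else if (length(partials) > 1L) {
    call <- "ambiguous"
    causative <- NA_character_
  } else {
    call <- "none"
    causative <- NA_character_
  }
  structure(list(mutant_id = mutant_id, causative_variant_id = causative,
                 call = call, tallies = tallies),
            class = "deconvolution_call")
}

#' @export
print.deconvolution_call <- function(x, ...) {
  cat(sprintf("<deconvolution_call> %s: %s%s\n", x$mutant_id, x$call,
              if (!is.na(x$causative_variant_id))
                paste0(" (", x$causative_variant_id, ")") else ""))
  print(x$tallies)
  invisible(x)
}

#' Write a deconvolution call to TSV
#'
#' @param call A [call_causative()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call <- function(call, path) {
  t <- call$tallies
  t$mutant_id <- call$mutant_id
  t$call <- call$call
  t$causative_variant_id <- if (is.na(call$causative_variant_id)) "" else
    call$causative_variant_id
  cols <- c("mutant_id", "call", "causative_variant_id", "group",
            "variant_id", "n_wells", "reverted", "intermediate",
            "mutant_like")
  write_tsv(format_num_df(t[cols]), path)
}

#' Candidate marker-tagged mutant alleles in the causative group
#'
#' Transduction only partially links the marker with the mutation: a
#' fraction `1 - f` of the causative group's transductants keep the
#' (un-reverted) mutant allele now linked to the selectable cassette.
#' These wells are candidate tagged alleles for a verification
#' transduction into a clean background.
#'
#' @param labels data.frame with `well_id`, `group`, `label`.
#' @param plan A [build_plan()] result.
#' @param causative_group Marker allele of the causative group.
#' @return List with `candidate_wells` (well ids labelled mutant-like in
#'   the causative group), `expected_tagged_fraction` (`1 - f` under the
#'   plan's predicted frequency), `observed_fraction`, and `advisory`
#'   (non-`NA` when every well reverted and no tagged candidate remains).
#' @export
linked_allele_report <- function(labels, plan, causative_group) {
  idx <- match(causative_group, plan$marker_allele)
  if (is.na(idx)) stop("causative group absent from plan: ", causative_group)
  grp <- labels[labels$group == causative_group, , drop = FALSE]
  if (!nrow(grp)) stop("no wells for causative group ", causative_group)
  cand <- grp$well_id[grp$label == "mutant-like"]
  list(candidate_wells = cand,
       expected_tagged_fraction = 1 - plan$predicted_freq[idx],
       observed_fraction = length(cand) / nrow(grp),
       advisory = if (!length(cand))
         "all transductants reverted; no marker-tagged mutant allele available"
       else NA_character_)
}
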
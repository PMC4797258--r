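# Poisson mutagenesis dose model and Monte-Carlo simulation of the full
# forward-genomic screen + transductional deconvolution workflow, plus the
# synthetic fixture generator used throughout the package.

#' Mutagenesis dose model
#'
#' Chemical point mutagenesis at a fixed dose produces a Poisson-distributed
#' number of mutations per genome with mean `lambda`.
#'
#' @param lambda Mean mutations per genome (non-negative).
#' @return Object of class `dose_model`.
#' @export
dose_model <- function(lambda) {
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0) {
    stop("lambda must be a single non-negative number")
  }
  structure(list(lambda = as.numeric(lambda)), class = "dose_model")
}

#' Probabilities of 0, 1, and >1 mutations per genome
#'
#' Under Poisson(`lambda`) mutagenesis: `P0 = exp(-lambda)`,
#' `P1 = lambda * exp(-lambda)`, `Pmore = 1 - P0 - P1`.
#'
#' @param dose A [dose_model()] (or a bare lambda).
#' @return Named list `P0`, `P1`, `Pmore` summing to 1.
#' @examples
#' mutation_count_probabilities(dose_model(6))
#' @export
mutation_count_probabilities <- function(dose) {
  if (!inherits(dose, "dose_model")) dose <- dose_model(dose)
  p0 <- exp(-dose$lambda)
  p1 <- dose$lambda * exp(-dose$lambda)
  list(P0 = p0, P1 = p1, Pmore = 1 - p0 - p1)
}

#' Dose required so a target fraction of cells carries a mutation
#'
#' Inverts `1 - P0`: `lambda = -log(1 - fraction)`.
#'
#' @param min_mutated_fraction Target fraction of mutated clones, in
#'   `(0, 1)`.
#' @return The required Poisson mean.
#' @examples
#' dose_for_target(0.95)  # ~3 mutations/genome
#' @export
dose_for_target <- function(min_mutated_fraction) {
  if (any(min_mutated_fraction <= 0) || any(min_mutated_fraction >= 1)) {
    stop("min_mutated_fraction must be in (0, 1)")
  }
  -log(1 - min_mutated_fraction)
}

#' Stochastic replaced-fragment model of generalized transduction
#'
#' The replacement around the selected marker extends independently to each
#' side by a random length `X` with survival function
#' `P(X >= d) = (1 - d/L)^3` on `[0, L]` — so the marginal probability
#' that a locus at distance `d` is co-replaced equals the Wu frequency,
#' and replacement is nested: covering a far locus implies covering every
#' nearer locus on the same side.
#'
#' @param fragment_length_L Transducing segment length in bp.
#' @return Object of class `fragment_model`.
#' @export
fragment_model <- function(fragment_length_L = 1e5) {
  structure(list(fragment_length_L =
                   linkage_model(fragment_length_L)$fragment_length_L),
            class = "fragment_model")
}

#' Sample per-side replacement extents
#'
#' Inverse-CDF sampling: `X = L * (1 - U^(1/3))` with `U ~ Uniform(0, 1)`.
#' Draws from the current R random number stream; seed it with
#' [set.seed()] for reproducibility.
#'
#' @param model A [fragment_model()].
#' @param n Number of transduction events.
#' @return data.frame with columns `left_bp` and `right_bp`, the
#'   independent extents (in `[0, L]`) on each side of the marker.
#' @export
sample_replacement_extent <- function(model, n = 1L) {
  stopifnot(inherits(model, "fragment_model"))
  L <- model$fragment_length_L
  data.frame(left_bp = L * (1 - stats::runif(n)^(1 / 3)),
             right_bp = L * (1 - stats::runif(n)^(1 / 3)))
}

#' Configuration of a simulated forward-genomic screen
#'
#' @param genome A [genome_map()].
#' @param lambda Mean mutations per genome (mutagenesis dose).
#' @param causative_fraction Probability that an individual mutation
#'   confers the screened phenotype.
#' @param detection_sensitivity Per-mutation probability that the WGS
#'   pipeline detects it.
#' @param n_picks Transductants picked per transduction plate.
#' @param revertant_threshold Minimum revertant wells for a causative call.
#' @param n_reps Monte-Carlo repetitions.
#' @param seed Mandatory integer seed for the single PRNG stream.
#' @param fragment_length_L Transducing segment length in bp.
#' @param n_mutants Genomes to draw in [simulate_mutant_genomes()].
#' @param single_causative If `TRUE`, [run_deconvolution_sim()] conditions
#'   each repetition on a mutant whose genome carries exactly one mutation
#'   (the causative one): the setting in which the closed-form
#'   `1 - (1 - f)^n` success prediction applies. The default `FALSE` keeps
#'   the full model, where additional non-causative mutations can share
#'   linkage with the causative one and produce ambiguous calls.
#' @return Object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(genome = genome_map(), lambda = 6,
                              causative_fraction = 0.05,
                              detection_sensitivity = 1,
                              n_picks = 22L, revertant_threshold = 2L,
                              n_reps = 1000L, seed,
                              fragment_length_L = 1e5,
                              n_mutants = 1000L,
                              single_causative = FALSE) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(inherits(genome, "genome_map"))
  probs <- c(causative_fraction = causative_fraction,
             detection_sensitivity = detection_sensitivity)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop(names(probs)[bad][1L], " must be in [0, 1]")
  if (lambda < 0) stop("lambda must be non-negative")
  if (n_picks < 1) stop("n_picks must be at least 1")
  if (n_reps < 1) stop("n_reps must be at least 1")
  structure(list(genome = genome, lambda = as.numeric(lambda),
                 causative_fraction = as.numeric(causative_fraction),
                 detection_sensitivity = as.numeric(detection_sensitivity),
                 n_picks = as.integer(n_picks),
                 revertant_threshold = as.integer(revertant_threshold),
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 fragment_length_L = as.numeric(fragment_length_L),
                 n_mutants = as.integer(n_mutants),
                 single_causative = isTRUE(single_causative)),
            class = "screen_sim_config")
}

# One mutant genome: Poisson(lambda) mutations at iid uniform integer
# positions, each independently causative. Draws from the current stream.
.draw_genome <- function(lambda, causative_fraction, G) {
  k <- stats::rpois(1L, lambda)
  pos <- if (k > 0) floor(stats::runif(k, 1, G + 1)) else numeric(0)
  list(positions = pos,
       causative = if (k > 0) stats::runif(k) < causative_fraction
                   else logical(0))
}

#' Simulate mutagenized genomes and the phenotype screen
#'
#' Draws `n_mutants` genomes with Poisson(`lambda`) mutations at i.i.d.
#' uniform positions; each mutation is independently causative with
#' probability `causative_fraction`. A genome passes the screen iff it
#' carries at least one causative mutation.
#'
#' @param config A [screen_sim_config()].
#' @return List with `genomes` (each: `positions`, `causative`,
#'   `screened`), `n_screened`, and `retention` (screened fraction).
#' @export
simulate_mutant_genomes <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  set.seed(config$seed)
  G <- config$genome$length_bp
  genomes <- lapply(seq_len(config$n_mutants), function(i) {
    g <- .draw_genome(config$lambda, config$causative_fraction, G)
    g$screened <- any(g$causative)
    g
  })
  n_scr <- sum(vapply(genomes, `[[`, TRUE, "screened"))
  list(genomes = genomes, n_screened = n_scr,
       retention = n_scr / config$n_mutants)
}

#' Thin WGS detection applied to a mutation set
#'
#' Each mutation is retained independently with probability `sensitivity`.
#' Draws from the current R random number stream.
#'
#' @param mutations Vector (or data.frame) of mutations.
#' @param sensitivity Per-mutation detection probability in `[0, 1]`.
#' @return Logical vector: `TRUE` for detected mutations.
#' @export
simulate_detection <- function(mutations, sensitivity) {
  if (sensitivity < 0 || sensitivity > 1) {
    stop("sensitivity must be in [0, 1]")
  }
  n <- if (is.data.frame(mutations)) nrow(mutations) else length(mutations)
  stats::runif(n) < sensitivity
}

#' Simulate transduction of a marked donor segment into a mutant recipient
#'
#' For each pick, left and right replacement extents are drawn around the
#' marker reference point; a recipient mutation is replaced by wild-type
#' donor sequence iff its signed circular offset from the marker falls
#' within the replaced arc. The pick's phenotype reverts iff every
#' causative mutation was replaced. Draws from the current stream.
#'
#' @param mutation_positions Recipient mutation positions (bp).
#' @param causative Logical vector marking the causative mutations.
#' @param marker_pos Marker reference position (bp; may be half-integral).
#' @param model A [fragment_model()].
#' @param n_picks Number of transductants.
#' @param genome A [genome_map()].
#' @return List with `replaced` (`n_picks` x `length(mutation_positions)`
#'   logical matrix) and `reverted` (logical vector of length `n_picks`).
#' @export
simulate_transduction <- function(mutation_positions, causative, marker_pos,
                                  model, n_picks, genome) {
  stopifnot(inherits(model, "fragment_model"),
            inherits(genome, "genome_map"))
  G <- genome$length_bp
  ext <- sample_replacement_extent(model, n_picks)
  k <- length(mutation_positions)
  if (k == 0L) {
    return(list(replaced = matrix(logical(0), nrow = n_picks, ncol = 0L),
                reverted = rep(TRUE, n_picks)))
  }
  off <- (mutation_positions - marker_pos) %% G
  right_side <- off <= G / 2
  d <- ifelse(right_side, off, G - off)
  # replaced[pick, mut]
  replaced <- matrix(FALSE, nrow = n_picks, ncol = k)
  for (j in seq_len(k)) {
    replaced[, j] <- if (right_side[j]) ext$right_bp >= d[j]
                     else ext$left_bp >= d[j]
  }
  reverted <- if (any(causative)) {
    rowSums(!replaced[, causative, drop = FALSE]) == 0L
  } else {
    rep(TRUE, n_picks)
  }
  list(replaced = replaced, reverted = reverted)
}

#' Plate noise model for simulated re-screens
#'
#' Well readings are log-normal around a class mean: reverted wells around
#' the wild-type level, un-reverted wells around the mutant level.
#'
#' @param wt_level,mutant_level Relative-fluorescence class means
#'   (arbitrary units; the defaults mimic an SOS reporter elevated ~8x in
#'   the mutant).
#' @param log_sd Gaussian noise SD on the log scale (0 = noiseless).
#' @return List with `wt_log_mean`, `mut_log_mean`, `log_sd`.
#' @export
plate_noise_model <- function(wt_level = 1000, mutant_level = 8000,
                              log_sd = 0.1) {
  if (wt_level <= 0 || mutant_level <= 0) stop("levels must be positive")
  if (log_sd < 0) stop("log_sd must be non-negative")
  list(wt_log_mean = log(wt_level), mut_log_mean = log(mutant_level),
       log_sd = as.numeric(log_sd))
}

#' Monte-Carlo simulation of the full deconvolution workflow
#'
#' Each repetition draws a mutagenized genome that passes the phenotype
#' screen, thins its mutations through imperfect WGS detection, plans one
#' transduction per detected variant against the marker library, simulates
#' `n_picks` transductants per planned marker under the replaced-fragment
#' model, synthesizes plate readings (reverted wells at the wild-type
#' level, the rest at the mutant level, log-normal noise), classifies the
#' wells, and calls the causative variant. Success means a `full` call
#' naming a truly causative mutation.
#'
#' @param config A [screen_sim_config()].
#' @param library A [marker_library()] on the same genome.
#' @param noise A [plate_noise_model()].
#' @return Object of class `simulation_summary`: `n_reps`, `successes`,
#'   `success_rate`, `wilson_ci` (95%), and `failure_modes`, a named
#'   vector of counts over `causative_undetected_by_WGS`,
#'   `no_revertant_among_picks`, `ambiguous_call`, `none_call`.
#' @export
run_deconvolution_sim <- function(config, library,
                                  noise = plate_noise_model()) {
  stopifnot(inherits(config, "screen_sim_config"),
            inherits(library, "marker_library"))
  if (nrow(library$markers) == 0L) stop("marker library is empty")
  if (config$causative_fraction <= 0) {
    stop("causative_fraction must be positive: no genome can pass the screen")
  }
  set.seed(config$seed)
  G <- config$genome$length_bp
  fmodel <- fragment_model(config$fragment_length_L)
  lmodel <- linkage_model(config$fragment_length_L)
  m_thr <- config$revertant_threshold
  wt_ref <- list(log_mean = noise$wt_log_mean,
                 log_sd = max(noise$log_sd, 1e-9))
  mut_ref <- list(log_mean = noise$mut_log_mean,
                  log_sd = max(noise$log_sd, 1e-9))
  modes <- c(causative_undetected_by_WGS = 0L,
             no_revertant_among_picks = 0L,
             ambiguous_call = 0L, none_call = 0L)
  successes <- 0L
  for (rep in seq_len(config$n_reps)) {
    # Rejection-sample a screened mutant: >= 1 causative mutation, or a
    # pure single-causative genome in validation mode.
    repeat {
      gen <- .draw_genome(config$lambda, config$causative_fraction, G)
      ok <- if (config$single_causative) {
        length(gen$positions) == 1L && gen$causative[1L]
      } else {
        any(gen$causative)
      }
      if (ok) break
    }
    detected <- simulate_detection(gen$positions,
                                   config$detection_sensitivity)
    if (!any(detected & gen$causative)) {
      modes["causative_undetected_by_WGS"] <-
        modes["causative_undetected_by_WGS"] + 1L
      next
    }
    det_pos <- gen$positions[detected]
    det_causative <- gen$causative[detected]
    variants <- data.frame(variant_id = sprintf("v%d", which(detected)),
                           pos_bp = det_pos, stringsAsFactors = FALSE)
    plan <- build_plan(variants, library, lmodel,
                       max_picks = config$n_picks)
    groups <- unique(plan$marker_allele)
    any_reverted <- FALSE
    labels <- vector("list", length(groups))
    for (gi in seq_along(groups)) {
      marker_pos <- .marker_ref_for_query(groups[gi], library)
      tr <- simulate_transduction(gen$positions, gen$causative, marker_pos,
                                  fmodel, config$n_picks, config$genome)
      any_reverted <- any_reverted || any(tr$reverted)
      lx <- ifelse(tr$reverted, noise$wt_log_mean, noise$mut_log_mean)
      if (noise$log_sd > 0) {
        lx <- lx + stats::rnorm(length(lx), 0, noise$log_sd)
      }
      labels[[gi]] <- data.frame(group = groups[gi],
                                 label = classify_log_rf(lx, wt_ref, mut_ref),
                                 stringsAsFactors = FALSE)
    }
    call <- call_causative(do.call(rbind, labels), plan, m = m_thr,
                           mutant_id = sprintf("rep%d", rep))
    true_ids <- variants$variant_id[det_causative]
    if (call$call == "full" && call$causative_variant_id %in% true_ids) {
      successes <- successes + 1L
    } else if (call$call %in% c("ambiguous", "full")) {
      modes["ambiguous_call"] <- modes["ambiguous_call"] + 1L
    } else if (!any_reverted) {
      modes["no_revertant_among_picks"] <-
        modes["no_revertant_among_picks"] + 1L
    } else {
      modes["none_call"] <- modes["none_call"] + 1L
    }
  }
  rate <- successes / config$n_reps
  structure(list(n_reps = config$n_reps, successes = successes,
                 success_rate = rate,
                 wilson_ci = wilson_interval(successes, config$n_reps),
                 failure_modes = modes),
            class = "simulation_summary")
}

# Midpoint reference for an intergenic insertion; for a gene replacement
# the side-aware edge rule is approximated by the midpoint here (the
# packaged and designed libraries are intergenic).
.marker_ref_for_query <- function(allele, library) {
  i <- match(allele, library$markers$allele_id)
  (library$markers$left_bp[i] + library$markers$right_bp[i]) / 2
}

#' Wilson 95% score interval for a binomial proportion
#'
#' @param successes,n Counts.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
wilson_interval <- function(successes, n, conf = 0.95) {
  if (n < 1) stop("n must be positive")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(sprintf("<simulation_summary> %d/%d successes (%.4f, 95%% CI %.4f-%.4f)\n",
              x$successes, x$n_reps, x$success_rate, x$wilson_ci[1],
              x$wilson_ci[2]))
  cat("failure modes:\n")
  for (nm in names(x$failure_modes)) {
    cat(sprintf("  %-28s %d\n", nm, x$failure_modes[[nm]]))
  }
  invisible(x)
}

#' Write a simulation summary to TSV
#'
#' @param summary A [run_deconvolution_sim()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulation_summary <- function(summary, path) {
  rec <- data.frame(n_reps = summary$n_reps, successes = summary$successes,
                    success_rate = summary$success_rate,
                    wilson_lower = summary$wilson_ci[["lower"]],
                    wilson_upper = summary$wilson_ci[["upper"]],
                    t(summary$failure_modes))
  write_tsv(format_num_df(rec), path)
}
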
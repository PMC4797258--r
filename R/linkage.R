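# Co-transduction linkage mathematics: the Wu frequency curve,
# nearest-marker search, genome-wide gene<->marker linkage tables, library
# coverage profiling, and separation probabilities for close mutations.

#' Co-transduction linkage model
#'
#' Generalized transduction by phage P1 replaces a contiguous chromosome
#' segment of up to roughly `L` = 100 kb around the selected marker. The
#' model predicts the probability that a locus at distance `d` from the
#' marker is co-replaced.
#'
#' @param fragment_length_L Transducing segment length in bp (default
#'   100,000 for phage P1).
#' @return Object of class `linkage_model`.
#' @export
linkage_model <- function(fragment_length_L = 1e5) {
  if (length(fragment_length_L) != 1L || !is.finite(fragment_length_L) ||
      fragment_length_L <= 0) {
    stop("fragment_length_L must be a single positive number")
  }
  structure(list(fragment_length_L = as.numeric(fragment_length_L)),
            class = "linkage_model")
}

#' Wu co-transduction frequency
#'
#' The classical mapping function for generalized transduction:
#' `f(d) = (1 - d/L)^3` for `0 <= d < L` and 0 beyond the transducing
#' segment length `L`. `f(0) = 1` (a marker always replaces itself) and f
#' decreases strictly to 0 at `d = L`. Distances may be real-valued
#' (marker reference points can be half-integral).
#'
#' @param distance_bp Non-negative distance(s) in bp.
#' @param model A [linkage_model()].
#' @return Co-transduction probability/probabilities in `[0, 1]`.
#' @examples
#' wu_frequency(20000, linkage_model())  # 0.512
#' @export
wu_frequency <- function(distance_bp, model = linkage_model()) {
  stopifnot(inherits(model, "linkage_model"))
  if (any(!is.finite(distance_bp)) || any(distance_bp < 0)) {
    stop("distance_bp must be non-negative")
  }
  L <- model$fragment_length_L
  ifelse(distance_bp >= L, 0, (1 - distance_bp / L)^3)
}

#' Nearest markers to a genomic position
#'
#' Ranks the `k` markers of a library closest to `pos_bp` under each
#' marker's distance convention (interval midpoint for intergenic
#' insertions, nearer edge for gene replacements), on the circular genome.
#' Ties are broken by lower `left_bp`, then lexicographic `allele_id`.
#'
#' @param pos_bp Query position in bp.
#' @param library A [marker_library()].
#' @param k Number of markers to return (capped at the library size).
#' @return data.frame with columns `allele_id`, `strain_id`, `left_bp`,
#'   `right_bp`, `kind`, `distance_bp`, sorted ascending by distance.
#' @export
nearest_markers <- function(pos_bp, library, k = 1L) {
  stopifnot(inherits(library, "marker_library"))
  if (nrow(library$markers) == 0L) stop("marker library is empty")
  if (length(k) != 1L || k < 1) stop("k must be a positive integer")
  .check_positions(pos_bp, library$genome, "query position")
  d <- marker_distances(pos_bp, library)
  m <- library$markers
  ord <- order(d, m$left_bp, m$allele_id)
  take <- utils::head(ord, min(as.integer(k), nrow(m)))
  out <- m[take, , drop = FALSE]
  out$distance_bp <- d[take]
  rownames(out) <- NULL
  out
}

#' Gene-by-marker linkage table
#'
#' For every gene, the `k` nearest markers with the distance from the gene
#' midpoint and the predicted co-transduction frequency. Rows whose
#' frequency is 0 (gene beyond the transducing segment of its nearest
#' markers) are retained and flagged.
#'
#' @param genes Annotation data.frame from [load_gene_features()] /
#'   [gene_features()].
#' @param library A [marker_library()].
#' @param model A [linkage_model()].
#' @param k Markers per gene.
#' @return data.frame with columns `gene_id`, `marker_allele`,
#'   `distance_bp` (rounded to integer bp), `predicted_freq`,
#'   `freq_percent` (rounded half-up), `unlinked` (logical flag for
#'   frequency 0).
#' @export
gene_linkage_table <- function(genes, library, model = linkage_model(),
                               k = 1L) {
  stopifnot(inherits(library, "marker_library"))
  if (!nrow(genes)) {
    return(data.frame(gene_id = character(), marker_allele = character(),
                      distance_bp = numeric(), predicted_freq = numeric(),
                      freq_percent = numeric(), unlinked = logical()))
  }
  per_gene <- lapply(seq_len(nrow(genes)), function(i) {
    nm <- nearest_markers(genes$midpoint_bp[i], library, k)
    data.frame(gene_id = genes$gene_id[i],
               marker_allele = nm$allele_id,
               distance_bp = nm$distance_bp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_gene)
  out$predicted_freq <- wu_frequency(out$distance_bp, model)
  out$freq_percent <- round_half_up(100 * out$predicted_freq)
  out$unlinked <- out$predicted_freq == 0
  out$distance_bp <- round_half_up(out$distance_bp)
  rownames(out) <- NULL
  out
}

#' Write a gene linkage table to TSV
#'
#' @param table Output of [gene_linkage_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linkage_table <- function(table, path) {
  cols <- c("gene_id", "marker_allele", "distance_bp", "predicted_freq",
            "freq_percent")
  write_tsv(format_num_df(table[cols]), path)
}

# Round half away from zero (2.5 -> 3), matching how percentages are
# reported; base round() rounds half to even.
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Full-precision, non-scientific number formatting for TSV output.
format_num_df <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      df[[col]] <- format(df[[col]], scientific = FALSE, trim = TRUE,
                          digits = 15)
    }
  }
  df
}

#' Marker-library coverage profile
#'
#' The worst-covered point of a circular genome tiled by markers lies at
#' the midpoint of the widest inter-marker gap, where the distance to the
#' nearest marker is half the gap. Gaps are measured between the facing
#' reference sides of consecutive markers (midpoints for intergenic
#' insertions; facing edges for gene replacements) including the
#' wraparound gap.
#'
#' @param library A [marker_library()].
#' @param model A [linkage_model()].
#' @return Object of class `coverage_summary`: list with `max_gap_bp`,
#'   `worst_position_bp` (gap midpoint, rounded to integer bp),
#'   `min_frequency` (= Wu frequency at half the widest gap), the flanking
#'   allele ids, and `gaps`, a per-gap data.frame.
#' @export
coverage_summary <- function(library, model = linkage_model()) {
  stopifnot(inherits(library, "marker_library"))
  m <- library$markers
  if (nrow(m) == 0L) stop("marker library is empty")
  g <- library$genome
  G <- g$length_bp
  mid <- (m$left_bp + m$right_bp) / 2
  # Reference coordinate seen from the right/left side of each marker.
  ref_right <- ifelse(m$kind == "gene-replacement", m$right_bp, mid)
  ref_left <- ifelse(m$kind == "gene-replacement", m$left_bp, mid)
  n <- nrow(m)
  nxt <- c(seq_len(n)[-1L], 1L)
  gap <- (ref_left[nxt] - ref_right) %% G
  if (n == 1L) gap <- G  # single marker: the whole circle is one gap
  midpoint <- (ref_right + gap / 2) %% G
  midpoint[midpoint == 0] <- G
  gaps <- data.frame(left_allele = m$allele_id,
                     right_allele = m$allele_id[nxt],
                     gap_bp = gap,
                     midpoint_bp = round_half_up(midpoint),
                     min_freq = wu_frequency(gap / 2, model),
                     stringsAsFactors = FALSE)
  worst <- which.max(gaps$gap_bp)
  structure(list(max_gap_bp = gaps$gap_bp[worst],
                 worst_position_bp = gaps$midpoint_bp[worst],
                 min_frequency = gaps$min_freq[worst],
                 left_allele = gaps$left_allele[worst],
                 right_allele = gaps$right_allele[worst],
                 gaps = gaps),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf(paste0("<coverage_summary> max gap %s bp (%s -> %s),",
                     " worst point %s, min co-transduction frequency %.4f",
                     " (%d%%)\n"),
              format(x$max_gap_bp, big.mark = ","), x$left_allele,
              x$right_allele, format(x$worst_position_bp, big.mark = ","),
              x$min_frequency, round_half_up(100 * x$min_frequency)))
  invisible(x)
}

#' Write a coverage summary to TSV
#'
#' One-record summary table; optionally the full per-gap table beside it.
#'
#' @param summary A [coverage_summary()] result.
#' @param path Output path for the summary record.
#' @param gaps_path Optional path for the per-gap table.
#' @return `path`, invisibly.
#' @export
write_coverage_summary <- function(summary, path, gaps_path = NULL) {
  rec <- data.frame(max_gap_bp = summary$max_gap_bp,
                    worst_position_bp = summary$worst_position_bp,
                    min_frequency = summary$min_frequency,
                    min_freq_percent = round_half_up(100 * summary$min_frequency),
                    left_allele = summary$left_allele,
                    right_allele = summary$right_allele)
  write_tsv(format_num_df(rec), path)
  if (!is.null(gaps_path)) write_tsv(format_num_df(summary$gaps), gaps_path)
  invisible(path)
}

#' Probability of separating two same-side mutations by transduction
#'
#' Two mutations in the same inter-marker interval, at distances `d_near`
#' and `d_far` from the marker, are separated by a transduction event that
#' replaces the near one but not the far one. Under the nested-replacement
#' geometry of a single transduced fragment this has probability
#' `wu(d_near) - wu(d_far)`.
#'
#' @param d_near_bp Distance of the nearer mutation from the marker (bp).
#' @param d_far_bp Distance of the farther mutation (bp);
#'   `d_near_bp <= d_far_bp`.
#' @param model A [linkage_model()].
#' @return Separation probability in `[0, 1]`.
#' @examples
#' separation_probability(20000, 30000)  # 0.169
#' @export
separation_probability <- function(d_near_bp, d_far_bp,
                                   model = linkage_model()) {
  if (any(d_near_bp < 0) || any(d_far_bp < 0)) {
    stop("distances must be non-negative")
  }
  if (any(d_near_bp > d_far_bp)) {
    stop("d_near_bp > d_far_bp: swap the arguments so the nearer ",
         "mutation comes first")
  }
  wu_frequency(d_near_bp, model) - wu_frequency(d_far_bp, model)
}
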
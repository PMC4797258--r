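# Design of new marker libraries: intergenic-region extraction and
# orientation classification, grid-and-snap placement of insertions at a
# target spacing, and validation against a minimum-linkage criterion.

#' Design specification for a marker library
#'
#' @param target_spacing_bp Target distance between consecutive insertions
#'   (default 50,000 bp, i.e. half the transducing segment length).
#' @param min_frequency Minimum acceptable co-transduction frequency at the
#'   worst-covered point (default 0.35).
#' @param model A [linkage_model()].
#' @return Object of class `design_spec`.
#' @export
design_spec <- function(target_spacing_bp = 5e4, min_frequency = 0.35,
                        model = linkage_model()) {
  stopifnot(inherits(model, "linkage_model"))
  if (target_spacing_bp <= 0) stop("target_spacing_bp must be positive")
  if (target_spacing_bp >= model$fragment_length_L) {
    stop("target_spacing_bp must be smaller than the transducing segment ",
         "length (", model$fragment_length_L, " bp), else full coverage ",
         "is impossible")
  }
  if (min_frequency < 0 || min_frequency > 1) {
    stop("min_frequency must be in [0, 1]")
  }
  structure(list(target_spacing_bp = as.numeric(target_spacing_bp),
                 min_frequency = as.numeric(min_frequency),
                 model = model),
            class = "design_spec")
}

#' Extract and classify intergenic regions of a circular genome
#'
#' Overlapping genes are first merged into opaque blocks; the regions
#' between consecutive blocks (including the wraparound region across the
#' origin) are classified by the strands of the flanking genes:
#' `(+, -)` convergent, `(-, +)` divergent, `(+, +)` or `(-, -)`
#' codirectional. Zero-length regions between abutting blocks are omitted.
#'
#' The wraparound region is reported with `start_bp > end_bp` and
#' `wraps = TRUE`; all other regions satisfy `start_bp <= end_bp`.
#'
#' @param genes Annotation data.frame ([gene_features()]).
#' @param genome A [genome_map()].
#' @return data.frame with columns `start_bp`, `end_bp`, `left_gene`,
#'   `right_gene`, `orientation`, `length_bp`, `wraps`.
#' @export
classify_intergenic_regions <- function(genes, genome) {
  stopifnot(inherits(genome, "genome_map"))
  G <- genome$length_bp
  if (!nrow(genes)) {
    warning("no genes: whole genome reported as one region with ",
            "undefined orientation")
    return(data.frame(start_bp = 1, end_bp = G, left_gene = NA_character_,
                      right_gene = NA_character_,
                      orientation = "undefined", length_bp = G,
                      wraps = FALSE, stringsAsFactors = FALSE))
  }
  .check_positions(genes$end_bp, genome, "gene end_bp")
  g <- genes[order(genes$start_bp, genes$end_bp), , drop = FALSE]
  # Merge overlapping genes into blocks; a block's outermost strands face
  # the neighbouring intergenic regions.
  blocks <- list()
  cur <- list(start = g$start_bp[1], end = g$end_bp[1],
              first_gene = g$gene_id[1], last_gene = g$gene_id[1],
              strand_left = g$strand[1], strand_right = g$strand[1])
  if (nrow(g) > 1L) for (i in 2:nrow(g)) {
    if (g$start_bp[i] <= cur$end) {  # overlap (abutting genes stay separate)
      if (g$end_bp[i] > cur$end) {
        cur$end <- g$end_bp[i]
        cur$last_gene <- g$gene_id[i]
        cur$strand_right <- g$strand[i]
      }
    } else {
      blocks[[length(blocks) + 1L]] <- cur
      cur <- list(start = g$start_bp[i], end = g$end_bp[i],
                  first_gene = g$gene_id[i], last_gene = g$gene_id[i],
                  strand_left = g$strand[i], strand_right = g$strand[i])
    }
  }
  blocks[[length(blocks) + 1L]] <- cur
  n <- length(blocks)
  regions <- lapply(seq_len(n), function(i) {
    b <- blocks[[i]]
    b2 <- blocks[[if (i == n) 1L else i + 1L]]
    start <- b$end + 1
    end <- b2$start - 1
    wraps <- i == n
    if (wraps) {
      start <- if (b$end == G) 1 else b$end + 1
      end <- if (b2$start == 1) G else b2$start - 1
      # region may or may not actually cross the origin after adjustment
      wraps <- start > end
      len <- (end - start) %% G + 1
      if (n == 1L && b$start == 1 && b$end == G) len <- 0  # block fills circle
    } else {
      len <- end - start + 1
    }
    if (len <= 0) return(NULL)
    data.frame(start_bp = start, end_bp = end,
               left_gene = b$last_gene, right_gene = b2$first_gene,
               orientation = .orientation_class(b$strand_right,
                                                b2$strand_left),
               length_bp = len, wraps = wraps, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, regions)
  if (is.null(out)) {
    out <- data.frame(start_bp = numeric(), end_bp = numeric(),
                      left_gene = character(), right_gene = character(),
                      orientation = character(), length_bp = numeric(),
                      wraps = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

.orientation_class <- function(left_strand, right_strand) {
  if (left_strand == "+" && right_strand == "-") "convergent"
  else if (left_strand == "-" && right_strand == "+") "divergent"
  else "codirectional"
}

# TRUE if pos lies inside the region (circular-aware; vectorised over
# regions).
.in_region <- function(pos, start, end, wraps) {
  ifelse(wraps, pos >= start | pos <= end, pos >= start & pos <= end)
}

#' Place marker insertions on a spacing grid, snapped into intergenic space
#'
#' Ideal insertion sites are laid on a regular grid of
#' `target_spacing_bp`; each is snapped to the nearest point (circular
#' distance, ties to the lower coordinate) that falls inside an intergenic
#' region. Sites with no intergenic point within half a transducing
#' segment are reported as unplaceable rather than raising an error. After
#' snapping, any adjacent marker pair whose gap midpoint falls below the
#' design's minimum frequency is reported as a coverage violation.
#'
#' @param regions Regions from [classify_intergenic_regions()].
#' @param spec A [design_spec()].
#' @param genome A [genome_map()].
#' @return List of class `placement` with elements `library` (a
#'   [marker_library()] of the placed insertions), `report` (per-ideal-site
#'   data.frame: `ideal_pos`, `snapped_pos`, `region_orientation`,
#'   `shift_bp`, `status`), and `violations` (per-gap data.frame of
#'   coverage violations, possibly empty).
#' @export
place_markers <- function(regions, spec, genome) {
  stopifnot(inherits(spec, "design_spec"), inherits(genome, "genome_map"))
  G <- genome$length_bp
  s <- spec$target_spacing_bp
  n_sites <- max(1L, floor(G / s))
  ideal <- (seq_len(n_sites) * s - 1) %% G + 1  # i*s, mapped into [1, G]
  L <- spec$model$fragment_length_L
  rep_rows <- lapply(ideal, function(p) {
    best <- .snap_to_regions(p, regions, genome)
    if (is.null(best) || best$dist > L / 2) {
      data.frame(ideal_pos = p, snapped_pos = NA_real_,
                 region_orientation = NA_character_, shift_bp = NA_real_,
                 status = "unplaceable", stringsAsFactors = FALSE)
    } else {
      data.frame(ideal_pos = p, snapped_pos = best$pos,
                 region_orientation = best$orientation,
                 shift_bp = best$dist, status = "placed",
                 stringsAsFactors = FALSE)
    }
  })
  report <- do.call(rbind, rep_rows)
  placed <- report[report$status == "placed", , drop = FALSE]
  dup <- duplicated(placed$snapped_pos)
  if (any(dup)) {
    report$status[report$status == "placed"][dup] <- "merged"
    placed <- placed[!dup, , drop = FALSE]
  }
  if (!nrow(placed)) stop("no marker could be placed in any intergenic region")
  pos <- sort(placed$snapped_pos)
  markers <- data.frame(
    allele_id = sprintf("d-%d", seq_along(pos)),
    strain_id = "proposed",
    left_bp = pos,
    right_bp = pmin(pos + 1, G),
    kind = "intergenic-insertion",
    stringsAsFactors = FALSE
  )
  library <- marker_library(markers, genome)
  cov <- coverage_summary(library, spec$model)
  viol <- cov$gaps[cov$gaps$min_freq < spec$min_frequency, , drop = FALSE]
  rownames(viol) <- NULL
  structure(list(library = library, report = report, violations = viol),
            class = "placement")
}

# Nearest point to p inside any region; returns list(pos, dist, orientation)
# or NULL when there are no regions.
.snap_to_regions <- function(p, regions, genome) {
  if (!nrow(regions)) return(NULL)
  best <- NULL
  for (r in seq_len(nrow(regions))) {
    st <- regions$start_bp[r]; en <- regions$end_bp[r]
    wraps <- isTRUE(regions$wraps[r])
    if (.in_region(p, st, en, wraps)) {
      cand <- list(pos = p, dist = 0, orientation = regions$orientation[r])
    } else {
      ds <- circular_distance(p, st, genome)
      de <- circular_distance(p, en, genome)
      # tie -> lower coordinate
      if (ds < de || (ds == de && st < en)) {
        cand <- list(pos = st, dist = ds, orientation = regions$orientation[r])
      } else {
        cand <- list(pos = en, dist = de, orientation = regions$orientation[r])
      }
    }
    if (is.null(best) || cand$dist < best$dist ||
        (cand$dist == best$dist && cand$pos < best$pos)) {
      best <- cand
    }
  }
  best
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf("<placement> %d markers placed (%d unplaceable sites, %d coverage violations)\n",
              nrow(x$library$markers),
              sum(x$report$status == "unplaceable"), nrow(x$violations)))
  invisible(x)
}

#' Write a placement report to TSV
#'
#' @param placement Result of [place_markers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_placement_report <- function(placement, path) {
  write_tsv(format_num_df(placement$report), path)
}

#' Orientation-class composition of a marker library
#'
#' Assigns each marker (by its reference midpoint) to the intergenic region
#' containing it and tallies the orientation classes of those regions. A
#' marker falling inside a gene block is a consistency error.
#'
#' @param library A [marker_library()].
#' @param regions Regions from [classify_intergenic_regions()].
#' @return data.frame with one row per orientation class: `orientation`,
#'   `n`, `fraction`, `percent` (rounded half-up).
#' @export
orientation_summary <- function(library, regions) {
  stopifnot(inherits(library, "marker_library"))
  if (!nrow(library$markers)) stop("marker library is empty")
  mids <- marker_reference_points(library)
  classes <- character(length(mids))
  for (i in seq_along(mids)) {
    hit <- which(.in_region(mids[i], regions$start_bp, regions$end_bp,
                            regions$wraps))
    if (!length(hit)) {
      stop("marker ", library$markers$allele_id[i],
           " does not fall in any intergenic region")
    }
    classes[i] <- regions$orientation[hit[1L]]
  }
  lev <- c("convergent", "codirectional", "divergent")
  n <- as.integer(table(factor(classes, levels = lev)))
  data.frame(orientation = lev, n = n, fraction = n / sum(n),
             percent = round_half_up(100 * n / sum(n)),
             stringsAsFactors = FALSE)
}

#' Validate a marker library against a design's coverage criterion
#'
#' Runs [coverage_summary()] and passes iff the minimum co-transduction
#' frequency at the worst-covered point is at least the design floor.
#'
#' @param library A [marker_library()].
#' @param spec A [design_spec()].
#' @return List of class `library_validation`: `pass` (logical),
#'   `min_frequency`, `floor`, `coverage` (the full [coverage_summary()]),
#'   and `failing_gaps` (gaps whose midpoint frequency is below the floor).
#' @export
validate_library <- function(library, spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  cov <- coverage_summary(library, spec$model)
  failing <- cov$gaps[cov$gaps$min_freq < spec$min_frequency, , drop = FALSE]
  rownames(failing) <- NULL
  structure(list(pass = cov$min_frequency >= spec$min_frequency,
                 min_frequency = cov$min_frequency,
                 floor = spec$min_frequency,
                 coverage = cov, failing_gaps = failing),
            class = "library_validation")
}

#' @export
print.library_validation <- function(x, ...) {
  cat(sprintf("<library_validation> %s: min frequency %.4f vs floor %.2f (%d gap(s) below floor)\n",
              if (x$pass) "PASS" else "FAIL", x$min_frequency, x$floor,
              nrow(x$failing_gaps)))
  invisible(x)
}
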
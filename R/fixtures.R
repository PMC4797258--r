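# Synthetic fixture generation: circular bacterial genome annotations,
# marker libraries at a target spacing, ENU-style mutant variant sets, and
# a simulated re-screen plate — written in the same dialects the loaders
# read.

#' Generate a synthetic circular-genome annotation
#'
#' Genes are laid end to start around the circle with log-normal lengths
#' and exponential intergenic gaps sized so that intergenic sequence makes
#' up roughly `intergenic_fraction` of the genome; strands are i.i.d. fair
#' coins. Draws from the current R random number stream.
#'
#' @param genome A [genome_map()].
#' @param mean_gene_bp Mean gene length (default 1,000 bp).
#' @param intergenic_fraction Target intergenic fraction of the genome
#'   (default 0.2).
#' @return Annotation data.frame as from [gene_features()].
#' @export
synthetic_annotation <- function(genome, mean_gene_bp = 1000,
                                 intergenic_fraction = 0.2) {
  stopifnot(inherits(genome, "genome_map"))
  if (intergenic_fraction <= 0 || intergenic_fraction >= 1) {
    stop("intergenic_fraction must be in (0, 1)")
  }
  G <- genome$length_bp
  mean_gap <- mean_gene_bp * intergenic_fraction / (1 - intergenic_fraction)
  genes <- list()
  pos <- 1 + round(stats::rexp(1, 1 / mean_gap))
  i <- 0L
  repeat {
    len <- max(3, round(stats::rlnorm(1, log(mean_gene_bp), 0.4)))
    if (pos + len - 1 > G) break
    i <- i + 1L
    genes[[i]] <- data.frame(
      gene_id = sprintf("g%04d", i),
      start_bp = pos, end_bp = pos + len - 1,
      strand = if (stats::runif(1) < 0.5) "+" else "-",
      stringsAsFactors = FALSE)
    pos <- pos + len + 1 + round(stats::rexp(1, 1 / mean_gap))
  }
  if (!length(genes)) stop("genome too short for even one gene")
  gene_features(do.call(rbind, genes), genome)
}

#' Generate an ENU-style mutant variant set
#'
#' Poisson(`lambda`) single-nucleotide variants at i.i.d. uniform
#' positions, with random REF bases and transition-free random ALT bases.
#' Draws from the current stream.
#'
#' @param genome A [genome_map()].
#' @param lambda Mean mutations per genome.
#' @return data.frame in the [load_variants()] layout.
#' @export
synthetic_variants <- function(genome, lambda = 6) {
  stopifnot(inherits(genome, "genome_map"))
  k <- stats::rpois(1L, lambda)
  bases <- c("A", "C", "G", "T")
  pos <- sort(floor(stats::runif(k, 1, genome$length_bp + 1)))
  ref <- sample(bases, k, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  data.frame(variant_id = sprintf("var%02d", seq_len(k)),
             pos_bp = pos, ref_allele = ref, alt_allele = unname(alt),
             var_class = rep("SNV", k), stringsAsFactors = FALSE)
}

# Minimal single-sample-free VCF 4.2 writer for SNV tables.
write_variants_vcf <- function(variants, genome, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", genome$name,
                   as.integer(genome$length_bp)),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  body <- if (nrow(variants)) {
    sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.", genome$name,
            as.integer(variants$pos_bp), variants$variant_id,
            variants$ref_allele, variants$alt_allele)
  }
  writeLines(c(hdr, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Annotation writers: 4-column TSV and minimal GFF3.
write_genes_tsv <- function(genes, path) {
  write_tsv(format_num_df(genes[c("gene_id", "start_bp", "end_bp",
                                  "strand")]), path)
}

write_genes_gff3 <- function(genes, genome, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", genome$name,
                   as.integer(genome$length_bp)))
  body <- sprintf("%s\ttransdecon\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  genome$name, as.integer(genes$start_bp),
                  as.integer(genes$end_bp), genes$strand, genes$gene_id)
  writeLines(c(hdr, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a key-value simulation config file
#'
#' @param config Named list of scalar values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- sprintf("%s = %s", names(config),
                   vapply(config, function(v) format(v, scientific = FALSE),
                          ""))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a flat key-value config file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values that
#' parse as numbers are returned numeric.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: '", ln, "'")
    val <- trimws(m[3L])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2L]]] <- if (!is.na(num)) num else val
  }
  out
}

#' Generate a self-consistent synthetic fixture set
#'
#' Writes, under `out_dir`: a gene annotation (`genes.tsv` and
#' `genes.gff3`), a marker library designed by [place_markers()]
#' (`markers.tsv`) plus its placement report, a mutant variant set
#' (`variants.vcf`), a plate file from one simulated transduction
#' experiment (`plate.tsv`, including `WT_REF`/`MUT_REF` control wells),
#' and a ready-to-run simulation config (`sim_config.txt`). The same seed
#' reproduces byte-identical files.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param genome_length_bp Genome length (default 500,000 bp for a compact
#'   but realistic toy replicon).
#' @param mean_gene_bp,intergenic_fraction Annotation shape parameters
#'   (see [synthetic_annotation()]).
#' @param spacing_bp Marker spacing target (default 50,000 bp).
#' @param lambda Mutations per genome for the variant set (default 6).
#' @param n_picks Transductants per group on the plate (default 22).
#' @param noise A [plate_noise_model()].
#' @return Named list of written file paths, invisibly.
#' @export
generate_fixtures <- function(seed, out_dir, genome_length_bp = 5e5,
                              mean_gene_bp = 1000,
                              intergenic_fraction = 0.2,
                              spacing_bp = 5e4, lambda = 6,
                              n_picks = 22L,
                              noise = plate_noise_model()) {
  if (missing(seed)) stop("seed is mandatory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  set.seed(as.integer(seed))
  genome <- genome_map("synthetic", genome_length_bp)
  genes <- synthetic_annotation(genome, mean_gene_bp, intergenic_fraction)
  regions <- classify_intergenic_regions(genes, genome)
  spec <- design_spec(spacing_bp, model = linkage_model())
  placement <- place_markers(regions, spec, genome)
  variants <- synthetic_variants(genome, lambda)

  paths <- list(
    genes_tsv = file.path(out_dir, "genes.tsv"),
    genes_gff3 = file.path(out_dir, "genes.gff3"),
    markers_tsv = file.path(out_dir, "markers.tsv"),
    placement_tsv = file.path(out_dir, "placement.tsv"),
    variants_vcf = file.path(out_dir, "variants.vcf"),
    plate_tsv = file.path(out_dir, "plate.tsv"),
    sim_config = file.path(out_dir, "sim_config.txt")
  )
  write_genes_tsv(genes, paths$genes_tsv)
  write_genes_gff3(genes, genome, paths$genes_gff3)
  write_marker_table(placement$library, paths$markers_tsv)
  write_placement_report(placement, paths$placement_tsv)
  write_variants_vcf(variants, genome, paths$variants_vcf)
  .write_plate_fixture(variants, placement$library, genome, n_picks,
                       noise, paths$plate_tsv)
  write_sim_config(list(genome_length_bp = genome_length_bp,
                        lambda = lambda, causative_fraction = 0.05,
                        detection_sensitivity = 0.9, n_picks = n_picks,
                        revertant_threshold = 2, n_reps = 200,
                        fragment_length_L = 1e5,
                        seed = as.integer(seed)),
                   paths$sim_config)
  invisible(paths)
}

# One simulated experiment: the first variant is causative; every planned
# marker group is transduced and read on a plate with control wells.
.write_plate_fixture <- function(variants, library, genome, n_picks, noise,
                                 path) {
  if (!nrow(variants)) {
    # plate with controls only
    plate <- .control_wells(noise)
    write_tsv(format_num_df(plate), path)
    return(invisible(path))
  }
  causative <- seq_len(nrow(variants)) == 1L
  plan <- build_plan(variants, library, max_picks = n_picks)
  fmodel <- fragment_model()
  rows <- list(.control_wells(noise))
  for (gr in unique(plan$marker_allele)) {
    marker_pos <- .marker_ref_for_query(gr, library)
    tr <- simulate_transduction(variants$pos_bp, causative, marker_pos,
                                fmodel, n_picks, genome)
    lx <- ifelse(tr$reverted, noise$wt_log_mean, noise$mut_log_mean)
    if (noise$log_sd > 0) lx <- lx + stats::rnorm(n_picks, 0, noise$log_sd)
    rows[[length(rows) + 1L]] <- data.frame(
      well_id = sprintf("%s_w%02d", gr, seq_len(n_picks)),
      group = gr, fluorescence = round(exp(lx), 3), od600 = 1,
      stringsAsFactors = FALSE)
  }
  write_tsv(format_num_df(do.call(rbind, rows)), path)
  invisible(path)
}

.control_wells <- function(noise, n = 8L) {
  wt <- exp(noise$wt_log_mean + stats::rnorm(n, 0, max(noise$log_sd, 0.02)))
  mut <- exp(noise$mut_log_mean + stats::rnorm(n, 0, max(noise$log_sd, 0.02)))
  data.frame(
    well_id = c(sprintf("wt%02d", seq_len(n)), sprintf("mut%02d", seq_len(n))),
    group = rep(c("WT_REF", "MUT_REF"), each = n),
    fluorescence = round(c(wt, mut), 3), od600 = 1,
    stringsAsFactors = FALSE)
}
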
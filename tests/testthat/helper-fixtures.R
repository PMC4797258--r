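# Shared in-code fixtures for the test suite.

# Point-marker library: each marker occupies a single coordinate so its
# reference point is exact.
point_library <- function(positions, genome, kind = "intergenic-insertion") {
  marker_library(data.frame(
    allele_id = sprintf("m%02d", seq_along(positions)),
    strain_id = "test",
    left_bp = positions, right_bp = positions,
    kind = kind, stringsAsFactors = FALSE), genome)
}

uniform_library <- function(genome, spacing) {
  point_library(seq(spacing, genome$length_bp, by = spacing), genome)
}

packaged_library <- function() {
  load_marker_table(system.file("extdata", "i_library_markers.tsv",
                                package = "transdecon"))
}

toy_genes <- function(...) {
  rows <- list(...)
  gene_features(do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], start_bp = as.numeric(r[[2]]),
               end_bp = as.numeric(r[[3]]), strand = r[[4]],
               stringsAsFactors = FALSE)
  })))
}

write_temp_vcf <- function(lines, contig = "chr", length_bp = 1e6) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig, length_bp),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  writeLines(c(hdr, lines), path)
  path
}
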
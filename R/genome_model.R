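# Circular-genome coordinate model and readers/writers for the tabular
# formats the tool touches: marker library TSV, gene annotation (GFF3 or
# 4-column TSV), and variant calls (VCF 4.x).

#' Default chromosome length (bp) for Escherichia coli K-12 MG1655
#'
#' Length of the U00096.3 reference sequence. Used as the default genome
#' length wherever a [genome_map()] is constructed implicitly.
#' @export
ECOLI_K12_LENGTH_BP <- 4641652L

#' Construct a circular genome coordinate model
#'
#' All coordinate arithmetic in the package flows through a `genome_map`:
#' positions are 1-based and must lie in `[1, length_bp]`; distances are
#' shortest-arc distances when `circular = TRUE`.
#'
#' @param name Text label for the replicon (used to match VCF contigs).
#' @param length_bp Positive integer length of the replicon in bp.
#' @param circular Logical; bacterial chromosomes are circular (default).
#' @return An object of class `genome_map` with fields `name`, `length_bp`,
#'   `circular`.
#' @examples
#' g <- genome_map("chr", 4641652)
#' circular_distance(9245, 4626645, g)
#' @export
genome_map <- function(name = "genome", length_bp = ECOLI_K12_LENGTH_BP,
                       circular = TRUE) {
  length_bp <- as.numeric(length_bp)
  if (length(length_bp) != 1L || !is.finite(length_bp) || length_bp < 1 ||
      length_bp != floor(length_bp)) {
    stop("genome length_bp must be a single positive integer, got: ",
         deparse(substitute(length_bp)))
  }
  structure(
    list(name = as.character(name), length_bp = length_bp,
         circular = isTRUE(circular)),
    class = "genome_map"
  )
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("<genome_map> %s: %s bp, %s\n", x$name,
              format(x$length_bp, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

.check_positions <- function(pos, genome, what = "position") {
  bad <- !is.finite(pos) | pos < 1 | pos > genome$length_bp
  if (any(bad)) {
    stop(sprintf("%s out of range [1, %d]: %s", what,
                 as.integer(genome$length_bp),
                 paste(utils::head(pos[bad], 5L), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Shortest distance between two positions on a (circular) genome
#'
#' On a circular replicon of length `G` the distance between positions `a`
#' and `b` is `min(|a - b|, G - |a - b|)`; on a linear replicon it is
#' `|a - b|`. Vectorised over `a` and `b`; positions may be half-integral
#' (marker reference points fall between two coordinates).
#'
#' @param a,b Positions in bp, each within `[1, length_bp]`.
#' @param genome A [genome_map()].
#' @return Numeric distance(s) in bp.
#' @export
circular_distance <- function(a, b, genome) {
  stopifnot(inherits(genome, "genome_map"))
  .check_positions(a, genome, "position a")
  .check_positions(b, genome, "position b")
  d <- abs(a - b)
  if (genome$circular) pmin(d, genome$length_bp - d) else d
}

## ---- marker library ---------------------------------------------------

MARKER_KINDS <- c("intergenic-insertion", "gene-replacement")

#' Construct a marker-insertion library
#'
#' An ordered library of selectable-cassette insertions (e.g. kanamycin
#' cassettes spaced ~50 kb around the chromosome). Each marker occupies the
#' interval `[left_bp, right_bp]`. Distances to an `intergenic-insertion`
#' are measured from the interval midpoint; distances to a
#' `gene-replacement` (a gene deleted and replaced by the cassette) are
#' measured from whichever edge of the replacement is nearer the query
#' locus.
#'
#' @param markers data.frame with columns `allele_id`, `strain_id`,
#'   `left_bp`, `right_bp`, `kind`.
#' @param genome A [genome_map()].
#' @return Object of class `marker_library`: list with `genome` and the
#'   validated `markers` data.frame sorted by `left_bp`.
#' @seealso [load_marker_table()], [write_marker_table()]
#' @export
marker_library <- function(markers, genome) {
  stopifnot(inherits(genome, "genome_map"))
  required <- c("allele_id", "strain_id", "left_bp", "right_bp", "kind")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols)) {
    stop("marker table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  markers <- as.data.frame(markers)[required]
  if (nrow(markers) == 0L) stop("marker library is empty")
  markers$allele_id <- as.character(markers$allele_id)
  markers$strain_id <- as.character(markers$strain_id)
  markers$kind <- as.character(markers$kind)
  for (col in c("left_bp", "right_bp")) {
    v <- markers[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v != floor(v))) {
      bad <- which(!is.numeric(v) | !is.finite(v) | v != floor(v))[1L]
      stop(sprintf("non-integer %s at marker row %d", col, bad))
    }
    markers[[col]] <- as.numeric(v)
  }
  dup <- duplicated(markers$allele_id)
  if (any(dup)) {
    stop("duplicate allele_id: ",
         paste(unique(markers$allele_id[dup]), collapse = ", "))
  }
  bad_kind <- !markers$kind %in% MARKER_KINDS
  if (any(bad_kind)) {
    stop("unknown marker kind at row ", which(bad_kind)[1L], ": ",
         markers$kind[bad_kind][1L])
  }
  if (any(markers$left_bp > markers$right_bp)) {
    stop("left_bp > right_bp at marker row ",
         which(markers$left_bp > markers$right_bp)[1L])
  }
  .check_positions(markers$left_bp, genome, "marker left_bp")
  .check_positions(markers$right_bp, genome, "marker right_bp")
  markers <- markers[order(markers$left_bp, markers$allele_id), , drop = FALSE]
  rownames(markers) <- NULL
  structure(list(genome = genome, markers = markers),
            class = "marker_library")
}

#' @export
print.marker_library <- function(x, ...) {
  cat(sprintf("<marker_library> %d markers on %s (%s bp)\n",
              nrow(x$markers), x$genome$name,
              format(x$genome$length_bp, big.mark = ",")))
  invisible(x)
}

#' Marker reference points for distance calculations
#'
#' Midpoint `(left_bp + right_bp)/2` for intergenic insertions (may be
#' half-integral). For gene replacements the reference depends on the query
#' side, so this returns the midpoint as a summary point; side-aware
#' distances are computed by [marker_distances()].
#'
#' @param library A [marker_library()].
#' @return Numeric vector of reference positions, one per marker.
#' @export
marker_reference_points <- function(library) {
  stopifnot(inherits(library, "marker_library"))
  (library$markers$left_bp + library$markers$right_bp) / 2
}

#' Distance from a position to every marker in a library
#'
#' Applies each marker's distance convention: interval midpoint for
#' `intergenic-insertion`, nearer interval edge for `gene-replacement`.
#'
#' @param pos_bp Single position in bp.
#' @param library A [marker_library()].
#' @return Numeric vector of distances (bp), one per marker.
#' @export
marker_distances <- function(pos_bp, library) {
  stopifnot(inherits(library, "marker_library"), length(pos_bp) == 1L)
  g <- library$genome
  m <- library$markers
  mid <- (m$left_bp + m$right_bp) / 2
  d <- circular_distance(rep(pos_bp, nrow(m)), mid, g)
  repl <- m$kind == "gene-replacement"
  if (any(repl)) {
    dl <- circular_distance(rep(pos_bp, sum(repl)), m$left_bp[repl], g)
    dr <- circular_distance(rep(pos_bp, sum(repl)), m$right_bp[repl], g)
    d[repl] <- pmin(dl, dr)
  }
  d
}

#' Read a marker-insertion library from TSV
#'
#' Expects a UTF-8, LF-terminated TSV with header
#' `allele_id  strain_id  left_bp  right_bp  kind`. Rows are validated and
#' re-sorted by `left_bp`. The packaged 94-insertion intergenic library
#' (file `i_library_markers.tsv` under `extdata`) loads with this reader.
#'
#' @param path Path to the TSV file.
#' @param genome A [genome_map()]; defaults to the K-12 chromosome.
#' @return A [marker_library()].
#' @examples
#' lib <- load_marker_table(
#'   system.file("extdata", "i_library_markers.tsv", package = "transdecon"))
#' nrow(lib$markers)  # 94
#' @export
load_marker_table <- function(path, genome = genome_map()) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE),
    error = function(e) stop("cannot parse marker table ", path, ": ",
                             conditionMessage(e)))
  if (nrow(tab) == 0L) stop("marker table is empty: ", path)
  required <- c("allele_id", "strain_id", "left_bp", "right_bp", "kind")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("marker table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("left_bp", "right_bp")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (any(is.na(v))) {
      stop(sprintf("non-integer %s at row %d of %s", col,
                   which(is.na(v))[1L], path))
    }
    tab[[col]] <- v
  }
  marker_library(tab, genome)
}

#' Write a marker library to TSV
#'
#' Inverse of [load_marker_table()]: the written file reloads to an
#' identical library.
#'
#' @param library A [marker_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(library, path) {
  stopifnot(inherits(library, "marker_library"))
  m <- library$markers
  m$left_bp <- format(m$left_bp, scientific = FALSE, trim = TRUE)
  m$right_bp <- format(m$right_bp, scientific = FALSE, trim = TRUE)
  write_tsv(m, path)
  invisible(path)
}

# Deterministic TSV writer: tab-separated, LF line endings, no quoting.
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(lapply(df, as.character),
                                            sep = "\t")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

## ---- gene annotation --------------------------------------------------

#' Read gene features from GFF3 or a minimal 4-column TSV
#'
#' GFF3 input (detected by extension `.gff`, `.gff3` or a `##gff-version`
#' first line) is parsed with \pkg{ape} and restricted to features of type
#' `gene`; the `ID`/`Name`/`locus_tag` attribute (first available) becomes
#' the gene id. TSV input must have columns `gene_id`, `start_bp`,
#' `end_bp`, `strand` (header optional if exactly these four columns in
#' this order).
#'
#' Coordinates are 1-based inclusive; features may not wrap the origin.
#'
#' @param path Path to a GFF3 or TSV file.
#' @param genome Optional [genome_map()] used to bound coordinates.
#' @return data.frame with columns `gene_id`, `start_bp`, `end_bp`,
#'   `strand`, `midpoint_bp`.
#' @export
load_gene_features <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE) ||
    (length(first) && startsWith(first, "##gff-version"))
  if (is_gff) {
    gff <- ape::read.gff(path)
    gff <- gff[gff$type == "gene", , drop = FALSE]
    if (nrow(gff) == 0L) stop("no features of type 'gene' in ", path)
    ids <- vapply(as.character(gff$attributes), .gff_feature_id, "",
                  USE.NAMES = FALSE)
    genes <- data.frame(gene_id = ids,
                        start_bp = as.numeric(gff$start),
                        end_bp = as.numeric(gff$end),
                        strand = as.character(gff$strand),
                        stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                             colClasses = "character")
    if (ncol(tab) < 4L) stop("gene TSV needs 4 columns, found ", ncol(tab),
                             " in ", path)
    if (identical(tolower(tab[1, 1]), "gene_id")) tab <- tab[-1, , drop = FALSE]
    genes <- data.frame(gene_id = tab[[1]],
                        start_bp = suppressWarnings(as.numeric(tab[[2]])),
                        end_bp = suppressWarnings(as.numeric(tab[[3]])),
                        strand = tab[[4]],
                        stringsAsFactors = FALSE)
  }
  gene_features(genes, genome)
}

.gff_feature_id <- function(attr) {
  for (key in c("ID", "Name", "locus_tag")) {
    m <- regmatches(attr, regexec(paste0("(^|;)\\s*", key, "=([^;]+)"), attr))[[1]]
    if (length(m) == 3L) return(m[3L])
  }
  attr
}

#' Validate a gene table into the package's annotation form
#'
#' @param genes data.frame with `gene_id`, `start_bp`, `end_bp`, `strand`.
#' @param genome Optional [genome_map()] for coordinate bounds.
#' @return Validated data.frame with an added `midpoint_bp` column (the
#'   linkage reference point of each gene).
#' @export
gene_features <- function(genes, genome = NULL) {
  required <- c("gene_id", "start_bp", "end_bp", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols)) {
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  genes <- as.data.frame(genes)[required]
  genes$gene_id <- as.character(genes$gene_id)
  genes$strand <- as.character(genes$strand)
  for (col in c("start_bp", "end_bp")) {
    if (any(is.na(genes[[col]]))) {
      stop("non-numeric ", col, " at gene row ",
           which(is.na(genes[[col]]))[1L])
    }
    genes[[col]] <- as.numeric(genes[[col]])
  }
  # Tolerate the unicode minus that shows up in copy-pasted strand columns.
  genes$strand[genes$strand == "−"] <- "-"
  bad_strand <- !genes$strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop("unknown strand symbol at gene row ", which(bad_strand)[1L], ": '",
         genes$strand[bad_strand][1L], "'")
  }
  if (any(genes$start_bp < 1)) {
    stop("coordinates are 1-based; start_bp < 1 at gene row ",
         which(genes$start_bp < 1)[1L])
  }
  if (any(genes$start_bp > genes$end_bp)) {
    stop("start_bp > end_bp at gene row ",
         which(genes$start_bp > genes$end_bp)[1L],
         " (wraparound features are not supported)")
  }
  if (!is.null(genome)) .check_positions(genes$end_bp, genome, "gene end_bp")
  genes$midpoint_bp <- (genes$start_bp + genes$end_bp) / 2
  rownames(genes) <- NULL
  genes
}

## ---- variants ---------------------------------------------------------

#' Read candidate variants from a VCF
#'
#' Parses a VCF 4.x file (plain or bgzipped) with \pkg{vcfR}. Multi-allelic
#' records are split into one candidate per ALT allele; the variant class
#' is inferred from REF/ALT lengths (`SNV`, `insertion`, `deletion`). Only
#' single-contig input is accepted: all records must lie on one contig, and
#' when `contig` is given (default: the genome's name, unless
#' `contig = NULL`) the contig must match it.
#'
#' @param path Path to a VCF file.
#' @param genome A [genome_map()].
#' @param contig Expected contig name; `NULL` to accept whatever single
#'   contig the file uses.
#' @param pass_only If `TRUE`, keep only records whose FILTER is PASS or
#'   `.`; by default all records are loaded.
#' @return data.frame with columns `variant_id`, `pos_bp`, `ref_allele`,
#'   `alt_allele`, `var_class`.
#' @export
load_variants <- function(path, genome = genome_map(), contig = NULL,
                          pass_only = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF ", path, ": ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {  # single-record files come back as a vector
    fix <- matrix(fix, nrow = length(fix) > 0,
                  dimnames = list(NULL, names(fix)))
  }
  fx <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fx) == 0L) {
    return(data.frame(variant_id = character(), pos_bp = numeric(),
                      ref_allele = character(), alt_allele = character(),
                      var_class = character(), stringsAsFactors = FALSE))
  }
  contigs <- unique(fx$CHROM)
  if (length(contigs) > 1L) {
    stop("multi-contig VCF not supported; contigs seen: ",
         paste(contigs, collapse = ", "))
  }
  if (!is.null(contig) && !identical(contigs, contig)) {
    stop("contig mismatch: expected '", contig, "', VCF has: ",
         paste(contigs, collapse = ", "))
  }
  if (pass_only) {
    keep <- is.na(fx$FILTER) | fx$FILTER %in% c("PASS", ".")
    fx <- fx[keep, , drop = FALSE]
  }
  if (nrow(fx) == 0L) {
    return(data.frame(variant_id = character(), pos_bp = numeric(),
                      ref_allele = character(), alt_allele = character(),
                      var_class = character(), stringsAsFactors = FALSE))
  }
  alts <- strsplit(fx$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fx)), n_alt)
  out <- data.frame(
    pos_bp = as.numeric(fx$POS)[idx],
    ref_allele = fx$REF[idx],
    alt_allele = unlist(alts),
    stringsAsFactors = FALSE
  )
  if (any(out$ref_allele == out$alt_allele)) {
    stop("REF equals ALT at POS ",
         out$pos_bp[out$ref_allele == out$alt_allele][1L])
  }
  .check_positions(out$pos_bp, genome, "variant POS")
  rl <- nchar(out$ref_allele); al <- nchar(out$alt_allele)
  out$var_class <- ifelse(rl == al, "SNV",
                          ifelse(al > rl, "insertion", "deletion"))
  ids <- fx$ID[idx]
  no_id <- is.na(ids) | ids == "." | ids == ""
  ids[no_id] <- sprintf("var_%s_%s>%s", format(out$pos_bp[no_id],
                                               scientific = FALSE,
                                               trim = TRUE),
                        out$ref_allele[no_id], out$alt_allele[no_id])
  # Disambiguate ids shared across split ALT alleles of one record.
  ids <- make.unique(ids, sep = "_alt")
  out <- data.frame(variant_id = ids, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
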
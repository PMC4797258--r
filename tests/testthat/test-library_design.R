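test_that("intergenic regions are extracted and oriented on a 1 kb circle", {
  g <- genome_map("toy", 1000)
  genes <- toy_genes(list("A", 100, 400, "+"), list("B", 600, 900, "-"))
  regions <- classify_intergenic_regions(genes, g)
  expect_equal(nrow(regions), 2)
  inner <- regions[regions$start_bp == 401, ]
  expect_equal(inner$end_bp, 599)
  expect_equal(inner$orientation, "convergent")  # (+, -)
  wrap <- regions[regions$wraps, ]
  expect_equal(wrap$start_bp, 901)
  expect_equal(wrap$end_bp, 99)
  expect_equal(wrap$orientation, "divergent")    # (-, +)
  expect_equal(wrap$length_bp, 199)
})

test_that("codirectional regions and abutting genes are handled", {
  g <- genome_map("toy", 1000)
  genes <- toy_genes(list("A", 100, 300, "+"), list("B", 500, 900, "+"))
  regions <- classify_intergenic_regions(genes, g)
  expect_equal(regions$orientation[regions$start_bp == 301], "codirectional")

  abut <- toy_genes(list("A", 100, 300, "+"), list("B", 301, 900, "-"))
  r2 <- classify_intergenic_regions(abut, g)
  expect_equal(nrow(r2), 1)  # zero-length inner region omitted
  expect_true(r2$wraps)
})

test_that("overlapping genes merge into blocks with outermost strands", {
  g <- genome_map("toy", 2000)
  genes <- toy_genes(list("A", 100, 500, "+"), list("B", 400, 800, "-"),
                     list("C", 1200, 1500, "+"))
  regions <- classify_intergenic_regions(genes, g)
  expect_equal(nrow(regions), 2)
  inner <- regions[regions$start_bp == 801, ]
  # block A+B faces right with B's strand (-), C faces left with +
  expect_equal(inner$orientation, "divergent")
  expect_equal(inner$left_gene, "B")
  expect_equal(inner$right_gene, "C")
})

test_that("a gene-free annotation yields one flagged whole-genome region", {
  g <- genome_map("toy", 1000)
  empty <- gene_features(data.frame(gene_id = character(),
                                    start_bp = numeric(),
                                    end_bp = numeric(),
                                    strand = character()))
  expect_warning(regions <- classify_intergenic_regions(empty, g),
                 "undefined")
  expect_equal(regions$orientation, "undefined")
  expect_equal(regions$length_bp, 1000)
})

test_that("markers fall on the grid when the genome is almost all intergenic", {
  g <- genome_map("toy", 2e5)
  genes <- toy_genes(list("tiny", 1, 10, "+"))
  regions <- classify_intergenic_regions(genes, g)
  placement <- place_markers(regions, design_spec(5e4), g)
  expect_equal(placement$library$markers$left_bp,
               c(50000, 100000, 150000, 200000))
  expect_equal(nrow(placement$violations), 0)
  expect_true(all(placement$report$status == "placed"))
  expect_equal(placement$report$shift_bp, rep(0, 4))
})

test_that("an ideal site inside a gene snaps to the nearer region edge", {
  g <- genome_map("toy", 2e5)
  genes <- toy_genes(list("block", 45000, 55000, "+"))
  regions <- classify_intergenic_regions(genes, g)
  placement <- place_markers(regions, design_spec(5e4), g)
  r1 <- placement$report[placement$report$ideal_pos == 50000, ]
  expect_equal(r1$snapped_pos, 44999)  # 5001 bp either way; tie -> lower
  expect_equal(r1$shift_bp, 5001)
  others <- placement$report[placement$report$ideal_pos != 50000, ]
  expect_true(all(others$shift_bp == 0))
})

test_that("a gene block wider than the transducing segment is a violation", {
  g <- genome_map("toy", 2e5)
  genes <- toy_genes(list("huge", 20001, 170000, "+"))
  regions <- classify_intergenic_regions(genes, g)
  placement <- place_markers(regions, design_spec(5e4), g)
  expect_gte(nrow(placement$violations), 1)
  expect_lt(min(placement$violations$min_freq), 0.35)
  expect_true(any(placement$report$status == "unplaceable"))
})

test_that("placement is deterministic", {
  set.seed(55)
  g <- genome_map("toy", 3e5)
  genes <- synthetic_annotation(g, mean_gene_bp = 1000,
                                intergenic_fraction = 0.25)
  regions <- classify_intergenic_regions(genes, g)
  p1 <- place_markers(regions, design_spec(5e4), g)
  p2 <- place_markers(regions, design_spec(5e4), g)
  expect_identical(p1$library$markers, p2$library$markers)
  expect_identical(p1$report, p2$report)
})

test_that("placement achieves full coverage on gene-dense synthetic genomes", {
  seeds <- c(101, 202, 303)
  for (s in seeds) {
    set.seed(s)
    g <- genome_map("toy", 5e5)
    genes <- synthetic_annotation(g, mean_gene_bp = 1000,
                                  intergenic_fraction = 0.2)
    regions <- classify_intergenic_regions(genes, g)
    placement <- place_markers(regions, design_spec(5e4), g)
    expect_equal(nrow(placement$violations), 0)
    val <- validate_library(placement$library, design_spec(5e4))
    expect_true(val$pass)
  }
})

test_that("orientation_summary tallies classes and spots misplaced markers", {
  g <- genome_map("toy", 4000)
  genes <- toy_genes(list("A", 1, 500, "+"), list("B", 1000, 1500, "-"),
                     list("C", 2000, 2500, "-"), list("D", 3000, 3500, "+"))
  regions <- classify_intergenic_regions(genes, g)
  # regions: 501-999 (+,-) conv; 1501-1999 (-,-) codir; 2501-2999 (-,+) div;
  # 3501-4000 wrap (+,+) codir
  lib <- point_library(c(700, 750, 1600, 2600), g)
  os <- orientation_summary(lib, regions)
  expect_equal(os$n[os$orientation == "convergent"], 2L)
  expect_equal(os$percent, c(50, 25, 25))
  expect_equal(sum(os$fraction), 1)

  allconv <- orientation_summary(point_library(c(600, 700, 800), g), regions)
  expect_equal(allconv$percent, c(100, 0, 0))

  inside <- point_library(1200, g)  # inside gene B
  expect_error(orientation_summary(inside, regions), "m01")
})

test_that("orientation classes of fair-coin strands converge to 25/50/25", {
  set.seed(77)
  g <- genome_map("big", 4e6)
  genes <- synthetic_annotation(g, mean_gene_bp = 1000,
                                intergenic_fraction = 0.3)
  regions <- classify_intergenic_regions(genes, g)
  n <- nrow(regions)
  expect_gt(n, 1000)
  p <- table(factor(regions$orientation,
                    c("convergent", "codirectional", "divergent"))) / n
  # 4 sigma binomial tolerance
  tol <- 4 * sqrt(0.25 * 0.75 / n)
  expect_lt(abs(p[["convergent"]] - 0.25), tol)
  expect_lt(abs(p[["divergent"]] - 0.25), tol)
  expect_lt(abs(p[["codirectional"]] - 0.50), 4 * sqrt(0.5 * 0.5 / n))
})

test_that("validate_library applies the coverage floor", {
  g5 <- genome_map("toy", 5e5)
  val <- validate_library(uniform_library(g5, 5e4), design_spec(5e4, 0.35))
  expect_true(val$pass)
  expect_equal(val$min_frequency, 0.421875)

  lib <- packaged_library()
  val2 <- validate_library(lib, design_spec(5e4, 0.35))
  expect_false(val2$pass)
  # several gaps sit just under the 35% floor; the widest is i-4 -> i-5
  expect_true("i-4" %in% val2$failing_gaps$left_allele)
  worst <- val2$failing_gaps[which.max(val2$failing_gaps$gap_bp), ]
  expect_equal(worst$left_allele, "i-4")
  expect_equal(worst$right_allele, "i-5")

  val3 <- validate_library(lib, design_spec(5e4, 0))
  expect_true(val3$pass)
})
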
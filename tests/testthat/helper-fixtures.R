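# shared fixtures: built in code, no files

# small uniform genome for fast simulation tests: 6 chromosomes, ~955 cM
small_map <- function() uniform_genome_map(total_cM = 955, n_chrom = 6)

# one-chromosome map of given length (cM == Mbp at 1 cM/Mbp)
one_chrom_map <- function(cm = 100) {
  genetic_map(rep("1", 2), c(1, cm * 1e6), c(0, cm))
}

toy_segments <- function() {
  segment_table(
    carrier_a = c("A", "A", "B"),
    carrier_b = c(NA, NA, "C"),
    chrom = c("1", "2", "1"),
    start_bp = c(1e6, 5e6, 2e6),
    end_bp = c(3e6, 9e6, 8e6),
    start_cM = c(1, 5, 2),
    end_cM = c(3, 9, 8))
}

# random valid segment table for round-trip property tests
random_segments <- function(n, seed) {
  set.seed(seed)
  start_bp <- sample.int(1e8, n)
  len_bp <- sample.int(5e6, n)
  start_cM <- start_bp / 1e6
  ibd <- runif(n) < 0.5
  segment_table(
    carrier_a = sprintf("S%02d", sample.int(20, n, replace = TRUE)),
    carrier_b = ifelse(ibd, sprintf("T%02d", sample.int(20, n, replace = TRUE)),
                       NA_character_),
    chrom = as.character(sample.int(22, n, replace = TRUE)),
    start_bp = start_bp, end_bp = start_bp + len_bp,
    start_cM = start_cM, end_cM = start_cM + len_bp / 1e6)
}

# deterministic tiny carrier table for risk arithmetic
abc_carriers <- function() {
  carrier_table(
    data.frame(id = c("A", "B", "C"), group = "g1"),
    list(A = "g1gene", B = "g1gene", C = "g2gene"),
    gene_universe = c("g1gene", "g2gene"))
}
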
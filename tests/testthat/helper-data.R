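# small genotype-matrix builder for hand-constructed fixtures
make_gm <- function(gt, pos = seq_len(nrow(gt)) * 10L,
                    scaffold = "scaf_1", dp = NULL,
                    pops = c("A", "B"), scaffold_lengths = NULL) {
  n <- ncol(gt)
  stopifnot(n %% 2 == 0)
  half <- n / 2
  popmap <- tibble::tibble(
    sample = sprintf("s%02d", seq_len(n)),
    pop = rep(pops, each = half)
  )
  sites <- tibble::tibble(
    scaffold = rep_len(scaffold, nrow(gt)),
    pos = as.integer(pos),
    ref = "A", alt = "T"
  )
  storage.mode(gt) <- "integer"
  geno_matrix(sites, gt, popmap, dp = dp, scaffold_lengths = scaffold_lengths)
}

# dosage rows: each argument a per-sample dosage vector
gt_rows <- function(...) do.call(rbind, list(...))
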
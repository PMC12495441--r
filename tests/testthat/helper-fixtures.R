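# Shared toy fixtures; everything is generated in code, nothing on disk.

toy_net_config <- function(...) {
  dta_network_config(d_model = 8L, protein_width = 12L, encoder_layers = 1L,
                     decoder_layers = 2L, attention_heads = 2L,
                     feedforward_width = 16L, dropout = 0, conv_kernel = 1L,
                     ...)
}

toy_embedding_pair <- function(len_m = 5, len_p = 7, d = 8, dp = 12,
                               seed = 1) {
  withr::with_seed(seed, list(
    Xm = matrix(stats::rnorm(len_m * d), len_m, d),
    Xp = matrix(stats::rnorm(len_p * dp), len_p, dp)
  ))
}

# Minimal clean raw record passing every filter rule.
clean_record <- function(n = 1) {
  tibble::tibble(
    ligand_smiles = rep("CCO", n) , # acyclic but valid; mass/length via protein
    protein_sequence = rep(strrep("ACDEFGHIKLMNPQRSTVWY", 15), n),  # 300 aa
    mutations = NA_character_,
    organism = "Homo sapiens", kingdom = "eukaryota",
    temperature = 37, ph = 7.4,
    measure_kind = "Ki", value_nm = 100, relation = "exact",
    source_tags = ""
  )
}

# Plain percentile of the weight-replicated list: the brute-force oracle for
# integer-weight weighted percentiles (quantile type 7).
replication_percentile <- function(values, weights, q) {
  stats::quantile(rep(values, times = weights), q / 100, type = 7,
                  names = FALSE)
}

# O(n^2) loop oracle for the concordance index.
c_index_oracle <- function(pred, target) {
  num <- 0; den <- 0
  n <- length(pred)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (target[i] > target[j]) {
      den <- den + 1
      if (pred[i] > pred[j]) num <- num + 1
      else if (pred[i] == pred[j]) num <- num + 0.5
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Mid-rank Spearman oracle computed from first principles.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
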
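# Independent oracles, deliberately distinct from the package internals.

# Brute-force running-sum score: full prefix scan in exact integer units
# (a hit adds G - h, a miss subtracts h; true value = scaled / (h (G - h))),
# extremum of largest magnitude, earliest prefix wins ties.
es_oracle <- function(query, gene_set) {
  hits <- query$genes %in% gene_set
  h <- sum(hits)
  G <- length(query$genes)
  if (h == 0L) return(0)
  if (h == G) return(1)
  step <- ifelse(hits, G - h, -h)
  run <- cumsum(step)
  run[which.max(abs(run))] / (h * (G - h))
}

# ETS oracle composed of two brute-force running sums plus the zero rule.
ets_oracle <- function(query, sig) {
  eu <- es_oracle(query, sig$t_up)
  ed <- es_oracle(query, sig$t_down)
  if ((eu > 0 && ed > 0) || (eu < 0 && ed < 0)) 0 else (eu - ed) / 2
}

# Upper-tail hypergeometric probability by full combinatorial enumeration.
hyper_oracle <- function(N, K, m, k) {
  js <- seq.int(k, min(m, K))
  sum(choose(K, js) * choose(N - K, m - js)) / choose(N, m)
}

toy_signature <- function(t_up, t_down, target_id = "toy") {
  structure(list(target_id = target_id, t_up = t_up, t_down = t_down,
                 n = length(t_up)),
            class = "target_signature")
}

# A small ranked query over g1..gG with strictly decreasing metrics.
toy_query <- function(G, label = "toy") {
  ranked_query(paste0("g", seq_len(G)), as.numeric(G:1), label = label)
}

random_signature <- function(universe, n_up, n_down, target_id = "rnd") {
  pick <- sample(universe, n_up + n_down)
  toy_signature(pick[seq_len(n_up)],
                pick[seq.int(n_up + 1L, n_up + n_down)], target_id)
}

# Minimal connectivity-result table for the target-algebra tests.
toy_results <- function(target_id, nets, fdr) {
  data.frame(target_id = target_id, ets = nets / 10, p = fdr,
             nets = nets, fdr = fdr,
             up_matched = 5L, down_matched = 5L, stringsAsFactors = FALSE)
}
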
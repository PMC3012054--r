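# Shared fixture builders; everything is generated in code under fixed seeds.

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

toy_proteome <- function() {
  proteome(c(A = "MSPARQSPIK", B = "KKRKAAAAAA", C = "MSPGRWWWWW",
             D = "AAAAAAAAAA", E = "CCSPYKCCCC"))
}

# two-class dataset with a planted degenerate motif; class index of the
# target class is returned explicitly (label order is first-appearance)
planted_dataset <- function(master_seed, n = 2000L, n_target = 250L,
                            length_mean = 400L, length_sd = 80L,
                            pattern = "SP.[RK]", penetrance = 0.7,
                            position_mode = "uniform",
                            background_rate = 0) {
  prot <- random_proteome(n, length_mean, length_sd,
                          seed = derive_seed(master_seed, "proteome"))
  set.seed(derive_seed(master_seed, "classes"))
  target_ids <- sample(names(prot), n_target)
  labels <- ifelse(names(prot) %in% target_ids, "target", "background")
  bp <- behavior_discrete(names(prot), labels, prot)
  tc <- match("target", bp$labels) - 1L
  pl <- plant_motif(prot, bp, pattern, tc, penetrance,
                    position_mode = position_mode,
                    seed = derive_seed(master_seed, "plant"))
  out_prot <- pl$proteome
  if (background_rate > 0) {
    bc <- match("background", bp$labels) - 1L
    out_prot <- plant_motif(out_prot, bp, pattern, bc, background_rate,
                            position_mode = "uniform",
                            seed = derive_seed(master_seed, "plant_bg"))$proteome
  }
  list(proteome = out_prot, behavior = bp, truth = pl$truth,
       target_class = tc)
}

shuffled_labels <- function(ds, master_seed) {
  set.seed(derive_seed(master_seed, "label_shuffle"))
  cls <- sample(ds$behavior$class)
  behavior_discrete(ds$behavior$ids, ds$behavior$labels[cls + 1L],
                    ds$proteome)
}

# independent contingency-table MI oracle (entropy decomposition, base R)
mi_oracle <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  ent(rowSums(tab) / n) + ent(colSums(tab) / n) - ent(as.numeric(tab) / n)
}

# naive position-by-position scanning oracle
scan_oracle <- function(sequence, m) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  w <- m$width
  L <- length(chars)
  if (L < w) return(integer(0))
  hits <- integer(0)
  for (s in 0:(L - w)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!(chars[s + j] %in% m$sets[[j]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

random_motif <- function(max_set = 3) {
  w <- sample(2:5, 1)
  sets <- lapply(seq_len(w), function(j) {
    if (j > 1 && j < w && stats::runif(1) < 0.2) aa_alphabet()
    else sample(aa_alphabet(), sample(seq_len(max_set), 1))
  })
  motif(sets)
}

random_sequence <- function(len) {
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}
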
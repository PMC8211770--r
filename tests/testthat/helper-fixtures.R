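# shared fixtures and independent oracles

# random structure codes drawn from the registry alphabet
random_codes <- function(n_struct, min_len = 2, max_len = 8) {
  alphabet <- sidechain_registry()$code
  replicate(n_struct, {
    len <- sample(min_len:max_len, 1)
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  })
}

# independent brute-force composition search: plain nested loops and scalar
# arithmetic, no shared code with enumerate_compositions
oracle_compositions <- function(mz, residues, water, adduct_delta, tol,
                                bounds) {
  hits <- character(0)
  for (h in 0:bounds[["Hex"]])
    for (p in 0:bounds[["Pent"]])
      for (d in 0:bounds[["dHex"]])
        for (u in 0:bounds[["HexA"]])
          for (a in 0:bounds[["Ac"]]) {
            if (h + p + d + u == 0) next
            m <- h * residues[["Hex"]] + p * residues[["Pent"]] +
              d * residues[["dHex"]] + u * residues[["HexA"]] +
              a * residues[["Ac"]] + water + adduct_delta
            if (abs(m - mz) <= tol)
              hits <- c(hits, paste(h, p, d, u, a, sep = "."))
          }
  sort(hits)
}

comp_keys <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(apply(df[, c("Hex", "Pent", "dHex", "HexA", "Ac")], 1, paste,
             collapse = "."))
}

# residue classes terminal on a structure, from the sidechain chemistry
# alone (no mass arithmetic): used to check the fragment/infer roundtrip
chemistry_terminals <- function(codes) {
  map <- list(X = "Pent", L = "Hex", F = "dHex", S = "Pent", D = "Pent",
              B = "Pent", E = "dHex", Y = "HexA", P = c("Hex", "HexA"))
  tt <- union(character(0),
              unlist(map[intersect(unique(codes), names(map))]))
  n <- length(codes)
  if (n >= 2 && (codes[n] == "G" || codes[1] == "G")) tt <- union(tt, "Hex")
  sort(tt)
}

# Mesotaenium-like fucosylated/galactosylated panel used in the enzyme and
# differential tests
fucosylated_panel <- c(XFG = 100, XXFG = 100, XLFG = 100,
                       XLG = 100, XXLG = 100, XLLG = 100)

noiseless_config <- function(structures, seed = 1) {
  simulation_config(structures = structures, mz_jitter_sd = 0,
                    intensity_noise_cv = 0,
                    contaminant_hexose_range = c(0, 0),
                    decoy_peak_count = 0, seed = seed)
}
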
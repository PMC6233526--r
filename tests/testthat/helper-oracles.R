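# Independent oracles used across tests.

# byte-wise lexicographic minimum
lex_min <- function(x) sort(x, method = "radix")[1]

# Brute-force signature oracle: enumerate EVERY depth-first serialization of
# the height-bounded subgraph (no pruning, no canonical-order shortcuts) and
# take the lexicographic minimum.  Same grammar as the package (atom label,
# closure marks bond@visit-index sorted by visit index, parenthesised
# branches) but implemented by naive full enumeration in R.
oracle_signature <- function(mol, root, height) {
  bond_char <- c("1" = "-", "2" = "=", "3" = "#", "ar" = ":")
  n <- mol$n
  adj <- rep(list(integer()), n)
  bnd <- matrix("", n, n)
  if (nrow(mol$bonds)) {
    for (e in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$from[e]; j <- mol$bonds$to[e]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
      bnd[i, j] <- bnd[j, i] <- bond_char[[mol$bonds$order[e]]]
    }
  }
  # atoms within distance <= height
  dist <- rep(NA_integer_, n); dist[root] <- 0L; frontier <- root
  while (length(frontier)) {
    nxt <- integer()
    for (u in frontier) if (dist[u] < height) {
      for (v in adj[[u]]) if (is.na(dist[v])) { dist[v] <- dist[u] + 1L; nxt <- c(nxt, v) }
    }
    frontier <- nxt
  }
  keep <- which(!is.na(dist))

  all_strings <- function(vis, k, used, str, stack) {
    if (!length(stack)) return(str)
    u <- stack[length(stack)]
    S <- intersect(adj[[u]], keep)
    S <- S[vis[S] == 0L]
    if (!length(S)) {
      str2 <- if (length(stack) > 1L) paste0(str, ")") else str
      return(all_strings(vis, k, used, str2, stack[-length(stack)]))
    }
    unlist(lapply(S, function(v) {
      vis2 <- vis; vis2[v] <- k
      used2 <- used; used2[u, v] <- used2[v, u] <- TRUE
      piece <- paste0("(", bnd[u, v], mol$labels[v])
      cl <- intersect(adj[[v]], keep)
      cl <- cl[vis2[cl] > 0L & !used2[v, cl]]
      if (length(cl)) {
        cl <- cl[order(vis2[cl])]
        for (w in cl) {
          used2[v, w] <- used2[w, v] <- TRUE
          piece <- paste0(piece, bnd[v, w], "@", vis2[w])
        }
      }
      all_strings(vis2, k + 1L, used2, paste0(str, piece), c(stack, v))
    }))
  }
  vis <- integer(n); vis[root] <- 1L
  lex_min(all_strings(vis, 2L, matrix(FALSE, n, n), mol$labels[root], root))
}

# naive re-summation oracles for the efficiency metrics
oracle_of <- function(preds) {
  s <- 0
  for (i in seq_len(nrow(preds))) {
    s <- s + if (preds$truth[i] == "A") preds$p_N[i] else preds$p_A[i]
  }
  s / nrow(preds)
}
oracle_caof <- function(preds) {
  sa <- 0; sn <- 0; ma <- 0; mn <- 0
  for (i in seq_len(nrow(preds))) {
    if (preds$truth[i] == "A") { sa <- sa + preds$p_N[i]; ma <- ma + 1 }
    else { sn <- sn + preds$p_A[i]; mn <- mn + 1 }
  }
  sa / ma + sn / mn
}
oracle_mc <- function(preds, eps) {
  k <- 0
  for (i in seq_len(nrow(preds))) {
    if (preds$p_A[i] > eps && preds$p_N[i] > eps) k <- k + 1
  }
  k / nrow(preds)
}

# random chemistry-free molecular graphs (trees plus an occasional extra
# ring-closing edge), for permutation / conservation / oracle properties
random_molgraph <- function(n_atoms, seed) {
  set.seed(seed)
  el <- sample(c("C", "N", "O", "S", "Cl"), n_atoms, replace = TRUE,
               prob = c(0.6, 0.15, 0.15, 0.05, 0.05))
  ar <- rep(FALSE, n_atoms)
  ch <- sample(c(0L, 0L, 0L, 0L, 1L, -1L), n_atoms, replace = TRUE)
  if (n_atoms == 1) return(molgraph(el, ar, ch))
  from <- integer(); to <- integer()
  for (v in 2:n_atoms) { from <- c(from, sample(v - 1L, 1)); to <- c(to, v) }
  if (n_atoms >= 4 && runif(1) < 0.5) {   # one extra edge -> a cycle
    repeat {
      cand <- sample(n_atoms, 2)
      dup <- any((from == min(cand) & to == max(cand)))
      if (!dup) { from <- c(from, min(cand)); to <- c(to, max(cand)); break }
    }
  }
  ord <- sample(c("1", "1", "1", "2", "3"), length(from), replace = TRUE)
  molgraph(el, ar, ch, data.frame(from = from, to = to, order = ord))
}

permute_molgraph <- function(mol, perm) {
  inv <- order(perm)   # perm[i] = new position of old atom i
  molgraph(mol$element[inv], mol$aromatic[inv], mol$charge[inv],
           data.frame(from = perm[mol$bonds$from], to = perm[mol$bonds$to],
                      order = mol$bonds$order))
}

# small separable target dataset built from the synthetic generator
make_toy_dataset <- function(n_a = 40, n_n = 40, noise = 0, seed = 5,
                             target = "T1") {
  sp <- synthetic_spec(n_targets = 1, n_active = n_a, n_nonactive = n_n,
                       label_noise = noise, seed = seed)
  mols <- generate_molecules(sp, target)
  target_dataset(target, data.frame(
    smiles = mols$smiles, activity = mols$activity, assumed = FALSE,
    entry_id = sprintf("ID%04d", seq_len(nrow(mols))),
    stringsAsFactors = FALSE))
}

# activity-record data frame shorthand
rec <- function(target, entry_id, smiles, activity) {
  data.frame(target = target, entry_id = entry_id, smiles = smiles,
             activity = activity, stringsAsFactors = FALSE)
}
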
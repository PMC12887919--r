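# Independent oracles and fixture builders used across the suite.

# Hypergeometric upper tail by direct summation of binomial-coefficient
# products (exact in double precision for N <= 40; no logs involved).
hyper_upper_enum <- function(x, K, n, N) {
  if (x == 0) return(1)
  j <- seq.int(x, min(K, n))
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Planar convex-hull area by gift wrapping followed by the shoelace
# formula; independent of grDevices::chull.
giftwrap_hull_area <- function(xy) {
  n <- nrow(xy)
  start <- which.min(xy[, 1] + 1e-12 * xy[, 2])
  hull <- start
  repeat {
    cur <- hull[length(hull)]
    cand <- setdiff(seq_len(n), cur)
    nxt <- cand[1]
    for (k in cand[-1]) {
      cr <- (xy[nxt, 1] - xy[cur, 1]) * (xy[k, 2] - xy[cur, 2]) -
            (xy[nxt, 2] - xy[cur, 2]) * (xy[k, 1] - xy[cur, 1])
      d_nxt <- sum((xy[nxt, ] - xy[cur, ])^2)
      d_k <- sum((xy[k, ] - xy[cur, ])^2)
      if (cr < 0 || (cr == 0 && d_k > d_nxt)) nxt <- k
    }
    if (nxt == start) break
    hull <- c(hull, nxt)
    if (length(hull) > n) stop("gift wrapping failed to close")
  }
  h <- xy[hull, , drop = FALSE]
  i2 <- c(seq_len(nrow(h))[-1], 1)
  abs(sum(h[, 1] * h[i2, 2] - h[i2, 1] * h[, 2])) / 2
}

rigid_rotation_3d <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

skull_lm <- function(a, b, id = "S") {
  landmark_set(id, c("foramen_magnum_apex", "maxillae_junction"),
               rbind(a, b), role = "skull")
}

unit_square_molar <- function(rotate = NULL, shift = c(0, 0, 0)) {
  set.seed(101)
  interior <- cbind(runif(21, 0.05, 0.95), runif(21, 0.05, 0.95), 0)
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), interior)
  if (!is.null(rotate)) pts <- pts %*% t(rotate)
  pts <- sweep(pts, 2, shift, "+")
  landmark_set("M", sprintf("crown_%02d", 1:25), pts, role = "molar")
}

toy_design <- function() {
  specimen_design(c("T1", "T2", "C1", "C2", "T3", "T4", "C3", "C4"),
                  rep(c("group1", "group2"), each = 4),
                  rep(c("treatment", "treatment", "control", "control"), 2),
                  rep(c("L1", "L1", "L2", "L2"), 2))
}

# Small handcrafted batch with peptide-level data: per-protein abundances
# are sums of peptide intensities so protein and peptide tables agree.
toy_batch <- function(batch = "group1", design = toy_design(),
                      accessions = c("P1", "P2", "P3"),
                      q = c(0.01, 0.02, 0.03),
                      n_pep = c(3L, 3L, 3L), psms = c(10L, 10L, 10L),
                      seed = 1) {
  set.seed(seed)
  specs <- design$specimen_id[design$batch == batch]
  pep <- data.frame(accession = rep(accessions, n_pep),
                    peptide_id = unlist(lapply(n_pep, function(k)
                      sprintf("pep%d", seq_len(k)))),
                    stringsAsFactors = FALSE)
  for (s in specs) pep[[s]] <- 2^rnorm(nrow(pep), 20, 1)
  ab <- do.call(rbind, lapply(accessions, function(a)
    colSums(as.matrix(pep[pep$accession == a, specs]))))
  dimnames(ab) <- list(accessions, specs)
  quant <- data.frame(accession = accessions, gene = toupper(accessions),
                      description = "toy", q_value = q,
                      n_peptides = n_pep, n_psms = psms,
                      stringsAsFactors = FALSE)
  group_dataset(batch, quant, ab, design, peptides = pep)
}

# Random valid dataset for round-trip checks, with some missing cells.
random_batch <- function(n = 50, batch = "group1", seed = 99,
                         missing_frac = 0.1) {
  set.seed(seed)
  design <- toy_design()
  specs <- design$specimen_id[design$batch == batch]
  acc <- sprintf("R%03d", seq_len(n))
  ab <- matrix(2^rnorm(n * length(specs), 22, 2), n,
               dimnames = list(acc, specs))
  ab[runif(length(ab)) < missing_frac] <- NA
  keep_alive <- rowSums(!is.na(ab)) == 0
  ab[keep_alive, 1] <- 2^22
  quant <- data.frame(accession = acc, gene = paste0("G", seq_len(n)),
                      description = sprintf("random protein %d", seq_len(n)),
                      q_value = runif(n, 0, 0.05),
                      n_peptides = sample(2:10, n, replace = TRUE),
                      n_psms = sample(4:40, n, replace = TRUE),
                      stringsAsFactors = FALSE)
  group_dataset(batch, quant, ab, design)
}

# Minimal ratio-result rows for selection/summarization tests.
ratio_row <- function(accession, comparison_id, batch, log2_ratio = 0,
                      adj_p = 1, missing = FALSE, censored = FALSE,
                      cap = 3.32) {
  data.frame(accession = accession, comparison_id = comparison_id,
             batch = batch,
             raw_ratio = if (missing) NA_real_ else 2^log2_ratio,
             log2_ratio = if (missing) NA_real_ else log2_ratio,
             censored = censored,
             p_value = if (missing) NA_real_ else adj_p,
             adj_p_value = if (missing) NA_real_ else adj_p,
             missing = missing, stringsAsFactors = FALSE)
}
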
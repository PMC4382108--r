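# shared fixtures and independent oracles

# construct a marker_set directly from parental genotypes and offspring calls
make_marker_set <- function(p1, p2, geno, type = NULL, ids = NULL) {
  n <- ncol(geno)
  M <- nrow(geno)
  ids <- ids %||% sprintf("m%02d", seq_len(M))
  off <- sprintf("o%03d", seq_len(n))
  if (is.null(type)) {
    type <- vapply(seq_len(M), function(i) {
      a <- strsplit(p1[i], "/")[[1]]; b <- strsplit(p2[i], "/")[[1]]
      h1 <- a[1] != a[2]; h2 <- b[1] != b[2]
      if (h1 && !h2) "lm" else if (!h1 && h2) "np"
      else if (setequal(a, b)) "hk" else "fi"
    }, character(1))
  }
  mk <- data.frame(marker_id = ids, contig_id = "ctg1",
                   position = seq_len(M), p1 = p1, p2 = p2,
                   seg_type = type, stringsAsFactors = FALSE)
  dimnames(geno) <- list(ids, off)
  structure(list(markers = mk, geno = geno, offspring = off),
            class = "marker_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random two-marker pair with known simulation truth, any class combination
random_marker_pair <- function(n = 80, r = runif(1, 0, 0.45),
                               classes = sample(c("lm", "np", "hk", "fi"), 2,
                                                replace = TRUE),
                               missing = 0.05) {
  par_of <- function(cl) switch(cl,
    lm = list(c("A", "G"), c("A", "A")), np = list(c("A", "A"), c("A", "G")),
    hk = list(c("A", "G"), c("A", "G")), fi = list(c("A", "G"), c("C", "T")))
  pa <- par_of(classes[1]); pb <- par_of(classes[2])
  if (runif(1) < 0.5) pb[[1]] <- rev(pb[[1]])
  if (runif(1) < 0.5) pb[[2]] <- rev(pb[[2]])
  ga <- gb <- character(n)
  for (i in seq_len(n)) {
    t1a <- sample(1:2, 1); t2a <- sample(1:2, 1)
    t1b <- if (runif(1) < r) 3 - t1a else t1a
    t2b <- if (runif(1) < r) 3 - t2a else t2a
    ga[i] <- paste(sort(c(pa[[1]][t1a], pa[[2]][t2a])), collapse = "/")
    gb[i] <- paste(sort(c(pb[[1]][t1b], pb[[2]][t2b])), collapse = "/")
  }
  ga[runif(n) < missing] <- NA
  gb[runif(n) < missing] <- NA
  ms <- make_marker_set(
    p1 = c(paste(sort(pa[[1]]), collapse = "/"), paste(sort(pb[[1]]), collapse = "/")),
    p2 = c(paste(sort(pa[[2]]), collapse = "/"), paste(sort(pb[[2]]), collapse = "/")),
    geno = rbind(ga, gb), ids = c("a", "b"))
  list(ms = ms, r = r, classes = classes)
}

# independent two-point oracle: direct likelihood evaluated on an rf grid
# (step 1e-4) for all four phase configurations, enumerating transmission
# combinations straight from the parental allele pairs
grid_oracle_two_point <- function(ms, step = 1e-4) {
  p1 <- lapply(ms$markers$p1, function(z) strsplit(z, "/")[[1]])
  p2 <- lapply(ms$markers$p2, function(z) strsplit(z, "/")[[1]])
  combos_of <- function(g, P1, P2) {
    out <- list()
    for (c1 in 1:2) for (c2 in 1:2) {
      if (paste(sort(c(P1[c1], P2[c2])), collapse = "/") == g)
        out[[length(out) + 1L]] <- c(c1, c2)
    }
    unique(out)
  }
  i1 <- p1[[1]][1] != p1[[1]][2] && p1[[2]][1] != p1[[2]][2]
  i2 <- p2[[1]][1] != p2[[1]][2] && p2[[2]][1] != p2[[2]][2]
  if (!i1 && !i2) return(list(rf = 0.5, lod = 0))
  grid <- seq(0, 0.5, step)
  ok <- which(!is.na(ms$geno[1, ]) & !is.na(ms$geno[2, ]))
  best <- list(l = -Inf, r = 0.5); lhalf <- NULL
  for (f1 in c(FALSE, TRUE)) for (f2 in c(FALSE, TRUE)) {
    ll <- 0
    for (k in ok) {
      ca <- combos_of(ms$geno[1, k], p1[[1]], p2[[1]])
      cb <- combos_of(ms$geno[2, k], p1[[2]], p2[[2]])
      fk <- 0
      for (u in ca) for (v in cb) {
        term <- rep(1, length(grid))
        if (i1) term <- term * (if (xor(u[1] != v[1], f1)) grid else 1 - grid)
        if (i2) term <- term * (if (xor(u[2] != v[2], f2)) grid else 1 - grid)
        fk <- fk + term
      }
      ll <- ll + log(pmax(fk, 1e-300))
    }
    if (is.null(lhalf)) lhalf <- ll[length(ll)]
    w <- which.max(ll)
    if (ll[w] > best$l) best <- list(l = ll[w], r = grid[w])
  }
  list(rf = best$r, lod = max(0, (best$l - lhalf) / log(10)))
}

# union-find single-linkage oracle over an explicit edge list
unionfind_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (length(edges)) for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

# brute-force multinomial goodness-of-fit chi-square
chisq_oracle <- function(obs, probs) {
  e <- probs * sum(obs)
  x2 <- sum((obs - e)^2 / e)
  list(chi2 = x2, p = pchisq(x2, length(obs) - 1, lower.tail = FALSE))
}

# brute-force variant-form normalizer: strip common suffix then prefix,
# compare lengths
normalize_oracle <- function(ref, alt) {
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substring(ref, nchar(ref)) == substring(alt, nchar(alt))) {
    ref <- substring(ref, 1, nchar(ref) - 1)
    alt <- substring(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substring(ref, 1, 1) == substring(alt, 1, 1)) {
    ref <- substring(ref, 2); alt <- substring(alt, 2)
  }
  if (nchar(ref) == 1 && nchar(alt) == 1) "sub"
  else if (nchar(alt) < nchar(ref)) "del"
  else if (nchar(alt) > nchar(ref)) "ins"
  else "mnp"
}

# small gene-model data frame builder
genes_df <- function(ids, contig, start, end, strand = "+", source = "A") {
  data.frame(gene_id = ids, contig_id = contig, start = start, end = end,
             strand = strand, source = source, stringsAsFactors = FALSE)
}
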
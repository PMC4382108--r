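# ---------------------------------------------------------------------------
# Two-point linkage for outbred F1 (pseudo-testcross) markers.
#
# Every marker is reduced to a per-offspring "transmission state": an integer
# encoding which parental alleles the offspring can have received. For a pair
# of markers, the joint state cross-tabulation is a sufficient statistic for
# the two-point likelihood, whose per-category probability is (up to a
# constant that cancels in the LOD) a polynomial of degree <= 2 in the
# recombination fraction r, with coefficients fixed by the two segregation
# classes and the parental phase configuration. The likelihood is maximised
# by EM over the unobserved transmissions (ambiguous double-heterozygote
# offspring) jointly with an outer maximisation over the <= 4 phase
# configurations. All pairs of a given class combination are fitted
# simultaneously with matrix arithmetic.
# ---------------------------------------------------------------------------

# transmission combos per class and state: list of c(c1, c2), where c_p
# indexes the parent's two alleles and NA marks an uninformative parent
.class_combos <- list(
  lm = list(list(c(1L, NA)), list(c(2L, NA))),
  np = list(list(c(NA, 1L)), list(c(NA, 2L))),
  hk = list(list(c(1L, 1L)), list(c(1L, 2L), c(2L, 1L)), list(c(2L, 2L))),
  fi = list(list(c(1L, 1L)), list(c(1L, 2L)), list(c(2L, 1L)), list(c(2L, 2L)))
)

# which parents carry linkage information for a class pair
.inf_parents <- function(ca, cb) {
  c(ca %in% c("lm", "hk", "fi") && cb %in% c("lm", "hk", "fi"),
    ca %in% c("np", "hk", "fi") && cb %in% c("np", "hk", "fi"))
}

# product of two polynomials in r, both degree <= 1, result stored deg <= 2
.pmul <- function(a, b) {
  c(a[1] * b[1], a[1] * b[2] + a[2] * b[1],
    a[1] * b[3] + a[2] * b[2] + a[3] * b[1])
}

# per-category polynomial coefficients of the likelihood f and of the
# expected-recombinant numerator g, for one phase configuration
pair_polys <- function(ca, cb, flip = c(FALSE, FALSE)) {
  inf <- .inf_parents(ca, cb)
  A <- .class_combos[[ca]]; B <- .class_combos[[cb]]
  Ka <- length(A); Kb <- length(B)
  Fc <- matrix(0, Ka * Kb, 3); Gc <- matrix(0, Ka * Kb, 3)
  for (i in seq_len(Ka)) for (j in seq_len(Kb)) {
    k <- (i - 1L) * Kb + j
    for (u in A[[i]]) for (v in B[[j]]) {
      w <- c(1, 0, 0); nrec <- 0L
      for (p in 1:2) {
        if (!inf[p]) next
        rec <- xor(u[p] != v[p], flip[p])
        w <- .pmul(w, if (rec) c(0, 1, 0) else c(1, -1, 0))
        nrec <- nrec + rec
      }
      Fc[k, ] <- Fc[k, ] + w
      Gc[k, ] <- Gc[k, ] + nrec * w
    }
  }
  list(F = Fc, G = Gc, npar = sum(inf), inf = inf)
}

# evaluate K category polynomials at a vector of r: returns length(r) x K
.poly_eval <- function(co, r) {
  rep(1, length(r)) %o% co[, 1] + r %o% co[, 2] + (r * r) %o% co[, 3]
}

# Batched EM over pairs sharing one class combination and phase configuration.
# ncat: pairs x K count matrix. Returns r-hat and log-likelihood per pair.
.em_batch <- function(ncat, polys, starts = c(0.25, 0.05, 0.45),
                      tol = 1e-6, max_iter = 200L) {
  npair <- nrow(ncat)
  N <- rowSums(ncat) * polys$npar
  logl_at <- function(r, idx = seq_len(npair)) {
    f <- .poly_eval(polys$F, r)
    rowSums(ncat[idx, , drop = FALSE] * log(pmax(f, 1e-300)))
  }
  best_r <- rep(0.5, npair); best_l <- rep(-Inf, npair)
  for (r0 in starts) {
    r <- rep(r0, npair)
    act <- which(N > 0)
    it <- 0L
    while (length(act) && it < max_iter) {
      it <- it + 1L
      f <- .poly_eval(polys$F, r[act])
      g <- .poly_eval(polys$G, r[act])
      E <- rowSums(ncat[act, , drop = FALSE] * (g / pmax(f, 1e-300)))
      rn <- pmin(pmax(E / N[act], 1e-9), 0.5)
      conv <- abs(rn - r[act]) < tol
      r[act] <- rn
      act <- act[!conv]
    }
    l <- logl_at(r)
    upd <- l > best_l + 1e-12 | (abs(l - best_l) <= 1e-12 & r < best_r)
    best_r[upd] <- r[upd]; best_l[upd] <- l[upd]
  }
  list(r = best_r, logl = best_l, n = N)
}

# flip configurations to try: all combinations over informative parents
.flip_set <- function(inf) {
  if (sum(inf) == 0L) return(list(c(FALSE, FALSE)))
  opts <- lapply(1:2, function(p) if (inf[p]) c(FALSE, TRUE) else FALSE)
  gr <- expand.grid(p1 = opts[[1]], p2 = opts[[2]])
  lapply(seq_len(nrow(gr)), function(i) c(gr$p1[i], gr$p2[i]))
}

# fit all pairs of one class combination; ncat assembled by caller.
# Returns rf, lod (log10), phase index, informative meioses per pair.
.fit_class_pairs <- function(ncat, ca, cb) {
  inf <- .inf_parents(ca, cb)
  flips <- .flip_set(inf)
  base <- pair_polys(ca, cb, flips[[1]])
  l_half <- {
    f <- .poly_eval(base$F, rep(0.5, nrow(ncat)))
    rowSums(ncat * log(pmax(f, 1e-300)))
  }
  best <- NULL
  for (fi in seq_along(flips)) {
    polys <- if (fi == 1L) base else pair_polys(ca, cb, flips[[fi]])
    fit <- .em_batch(ncat, polys)
    if (is.null(best)) {
      best <- list(r = fit$r, logl = fit$logl, phase = rep(fi, nrow(ncat)), n = fit$n)
    } else {
      upd <- fit$logl > best$logl + 1e-9 |
        (abs(fit$logl - best$logl) <= 1e-9 & fit$r < best$r)
      best$r[upd] <- fit$r[upd]; best$logl[upd] <- fit$logl[upd]
      best$phase[upd] <- fi
    }
  }
  lod <- pmax((best$logl - l_half) / log(10), 0)
  rf <- best$r
  rf[best$n == 0] <- 0.5
  lod[best$n == 0] <- 0
  rf[rf < 1e-6] <- 0
  list(rf = rf, lod = lod, phase = best$phase, n = best$n, flips = flips)
}

#' Transmission-state encoding of a marker set
#'
#' Reduces each QC-passed marker to its segregation class (`lm`, `np`, `hk`,
#' `fi`) and an integer per-offspring transmission state (`NA` for no-call):
#' for single-het markers the transmitted allele of the informative parent;
#' for `hk` (ab x ab) markers the three genotype classes, the heterozygote
#' being ambiguous; for fully informative markers the four (P1, P2)
#' transmission pairs.
#'
#' @param ms a `marker_set`.
#' @return list with `class` (character) and `states` (integer matrix
#'   markers x offspring).
#' @keywords internal
marker_states <- function(ms) {
  M <- nrow(ms$markers)
  cls <- ms$markers$seg_type
  st <- matrix(NA_integer_, M, length(ms$offspring))
  for (m in seq_len(M)) {
    p1 <- split_geno(ms$markers$p1[m]); p2 <- split_geno(ms$markers$p2[m])
    type <- cls[m]
    map <- list()
    for (c1 in 1:2) for (c2 in 1:2) {
      g <- geno_str(p1[c1], p2[c2])
      map[[g]] <- unique(rbind(map[[g]], c(c1, c2)))
    }
    state_of <- vapply(names(map), function(g) {
      cmb <- map[[g]]
      if (type == "lm") cmb[1L, 1L]
      else if (type == "np") cmb[1L, 2L]
      else if (type == "hk") {
        if (nrow(cmb) > 1L) 2L else if (cmb[1L, 1L] == 1L) 1L else 3L
      } else (cmb[1L, 1L] - 1L) * 2L + cmb[1L, 2L]
    }, integer(1))
    st[m, ] <- unname(state_of[ms$geno[m, ]])
  }
  list(class = cls, states = st)
}

#' Two-point recombination fraction and LOD for one marker pair
#'
#' Maximises the joint likelihood over the recombination fraction
#' `rf` in `[0, 0.5]` and the (at most four) parental phase configurations by
#' expectation-maximization over unobserved transmissions, with restarts at
#' rf 0.25, 0.05 and 0.45 and ties across phases broken toward smaller rf.
#' The LOD score is `log10 L(rf-hat) / L(0.5)`. Offspring with a no-call at
#' either marker are excluded. Pairs informative in strictly different single
#' parents (P1-het x P2-het) carry no linkage information and return
#' `rf = 0.5`, `lod = 0`.
#'
#' @param a,b single-marker `marker_set` objects on the same offspring panel
#'   (subset a larger set with `ms[i]`).
#' @return list with `rf`, `lod`, `phase` (per-parent coupling/repulsion
#'   label, `NA` for uninformative parents), `informative_meioses`, and the
#'   two marker ids.
#' @examples
#' \dontrun{
#' pw <- estimate_two_point(ms[1], ms[2])
#' }
#' @export
estimate_two_point <- function(a, b) {
  am_check(inherits(a, "marker_set") && inherits(b, "marker_set"),
           "'a' and 'b' must be marker_set objects")
  am_check(nrow(a$markers) == 1L && nrow(b$markers) == 1L,
           "'a' and 'b' must each contain exactly one marker")
  am_check(identical(a$offspring, b$offspring),
           "markers come from different offspring panels")
  sa <- marker_states(a); sb <- marker_states(b)
  ca <- sa$class; cb <- sb$class
  ids <- c(a$markers$marker_id, b$markers$marker_id)
  inf <- .inf_parents(ca, cb)
  if (!any(inf)) {
    return(list(rf = 0.5, lod = 0, phase = c(P1 = NA, P2 = NA),
                informative_meioses = 0L, markers = ids))
  }
  Ka <- length(.class_combos[[ca]]); Kb <- length(.class_combos[[cb]])
  va <- sa$states[1L, ]; vb <- sb$states[1L, ]
  ok <- !is.na(va) & !is.na(vb)
  ncat <- matrix(0, 1L, Ka * Kb)
  if (any(ok)) {
    tab <- table(factor(va[ok], levels = seq_len(Ka)),
                 factor(vb[ok], levels = seq_len(Kb)))
    ncat[1L, ] <- as.vector(t(tab))  # row-major: (i-1)*Kb + j
  }
  fit <- .fit_class_pairs(ncat, ca, cb)
  flip <- fit$flips[[fit$phase[1L]]]
  phase <- ifelse(inf, ifelse(flip, "repulsion", "coupling"), NA_character_)
  names(phase) <- c("P1", "P2")
  list(rf = fit$rf[1L], lod = fit$lod[1L], phase = phase,
       informative_meioses = fit$n[1L], markers = ids)
}

#' All pairwise two-point linkage estimates
#'
#' Computes recombination fraction, LOD and informative-meiosis count for
#' every marker pair, batching pairs by segregation-class combination so the
#' joint-state cross-tabulations reduce to matrix products. P1-het x P2-het
#' pairs are uninformative and are reported at `rf = 0.5`, `lod = 0`.
#'
#' @param ms a `marker_set` of QC-passed markers.
#' @return object of class `pairwise_linkage`: symmetric matrices `rf`,
#'   `lod`, `n` (informative meioses) with marker ids as dimnames, plus the
#'   segregation class vector.
#' @export
pairwise_linkage <- function(ms) {
  am_check(inherits(ms, "marker_set"), "'ms' must be a marker_set")
  enc <- marker_states(ms)
  M <- nrow(ms$markers)
  ids <- ms$markers$marker_id
  rfM <- matrix(0.5, M, M, dimnames = list(ids, ids))
  lodM <- matrix(0, M, M, dimnames = list(ids, ids))
  nM <- matrix(0L, M, M, dimnames = list(ids, ids))
  diag(rfM) <- 0
  classes <- c("lm", "np", "hk", "fi")
  for (ai in seq_along(classes)) for (bi in ai:length(classes)) {
    ca <- classes[ai]; cb <- classes[bi]
    if (!any(.inf_parents(ca, cb))) next
    ia <- which(enc$class == ca); ib <- which(enc$class == cb)
    if (!length(ia) || !length(ib)) next
    Ka <- length(.class_combos[[ca]]); Kb <- length(.class_combos[[cb]])
    Ia <- lapply(seq_len(Ka), function(k) {
      x <- enc$states[ia, , drop = FALSE] == k
      x[is.na(x)] <- FALSE
      `storage.mode<-`(x, "numeric")
    })
    Ib <- lapply(seq_len(Kb), function(k) {
      x <- enc$states[ib, , drop = FALSE] == k
      x[is.na(x)] <- FALSE
      `storage.mode<-`(x, "numeric")
    })
    same <- identical(ca, cb)
    if (same) {
      sel <- which(upper.tri(matrix(0, length(ia), length(ia))), arr.ind = TRUE)
    } else {
      sel <- as.matrix(expand.grid(seq_along(ia), seq_along(ib)))
    }
    if (!nrow(sel)) next
    ncat <- matrix(0, nrow(sel), Ka * Kb)
    for (i in seq_len(Ka)) for (j in seq_len(Kb)) {
      C <- Ia[[i]] %*% t(Ib[[j]])
      ncat[, (i - 1L) * Kb + j] <- C[sel]
    }
    fit <- .fit_class_pairs(ncat, ca, cb)
    ra <- ia[sel[, 1L]]; rb <- ib[sel[, 2L]]
    rfM[cbind(ra, rb)] <- fit$rf; rfM[cbind(rb, ra)] <- fit$rf
    lodM[cbind(ra, rb)] <- fit$lod; lodM[cbind(rb, ra)] <- fit$lod
    nM[cbind(ra, rb)] <- fit$n; nM[cbind(rb, ra)] <- fit$n
  }
  structure(list(rf = rfM, lod = lodM, n = nM, class = enc$class, ids = ids),
            class = "pairwise_linkage")
}

#' @export
print.pairwise_linkage <- function(x, ...) {
  cat(sprintf("pairwise_linkage: %d markers, %d informative pairs (lod > 0)\n",
              length(x$ids), sum(x$lod[upper.tri(x$lod)] > 0)))
  invisible(x)
}
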
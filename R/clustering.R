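#' Microstate map sets
#'
#' A `mapset` holds K labeled microstate template topographies (each
#' zero-mean with unit GFP) plus provenance: the clustering algorithm,
#' derivation strategy, montage, and the global explained variance on the
#' maps it was derived from.
#'
#' @param maps K x channels numeric matrix.
#' @param labels Character class labels (unique), one per map.
#' @param algorithm `"taahc"` or `"kmeans"`.
#' @param strategy `"global"`, `"by_session"`, `"by_recording"`, or other
#'   provenance tag.
#' @param gev_on_source GEV achieved on the clustering inputs.
#' @return Object of class `mapset`.
#' @export
mapset <- function(maps, labels = NULL, algorithm = NA_character_,
                   strategy = NA_character_, gev_on_source = NA_real_) {
  maps <- as.matrix(maps)
  if (is.null(labels)) labels <- rownames(maps)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(maps)))
  if (anyDuplicated(labels)) stop("mapset labels must be unique")
  maps <- .gfp_normalize_rows(maps)
  rownames(maps) <- labels
  structure(list(maps = maps, labels = labels, algorithm = algorithm,
                 strategy = strategy, channel_labels = colnames(maps),
                 gev_on_source = gev_on_source),
            class = "mapset")
}

#' @export
print.mapset <- function(x, ...) {
  cat(sprintf("<mapset> %d maps [%s] x %d channels (%s, %s)%s\n",
              nrow(x$maps), paste(x$labels, collapse = ","), ncol(x$maps),
              x$algorithm, x$strategy,
              if (is.na(x$gev_on_source)) ""
              else sprintf(", source GEV %.3f", x$gev_on_source)))
  invisible(x)
}

# center rows and scale each to GFP 1; for such rows
# spatial correlation = (a %*% t(b)) / n_channels
.gfp_normalize_rows <- function(m) {
  m <- m - rowMeans(m)
  g <- sqrt(rowSums(m^2) / ncol(m))
  if (any(g == 0)) stop("constant map cannot be normalized")
  m / g
}

# mean of member maps after aligning each member's polarity to a reference
# map; returns a GFP-normalized map
.polarity_mean <- function(members, ref = NULL) {
  if (is.null(dim(members))) members <- matrix(members, nrow = 1)
  if (is.null(ref)) ref <- members[1, ]
  s <- sign(members %*% ref)
  s[s == 0] <- 1
  m <- colSums(members * as.numeric(s)) / nrow(members)
  .gfp_normalize_rows(matrix(m, nrow = 1))[1, ]
}

.as_maps_matrix <- function(maps) {
  if (inherits(maps, "peakset")) maps$maps else as.matrix(maps)
}

#' Topographic atomize-and-agglomerate hierarchical clustering (TAAHC)
#'
#' Every input map starts as its own cluster. At each step the "worst"
#' cluster — the one with the lowest summed absolute spatial correlation
#' between its members and its mean map — is atomized, and its members are
#' reassigned one at a time (in input order) to the surviving cluster
#' whose mean they correlate with most strongly (polarity-invariant), the
#' receiving cluster's mean being updated after each arrival. This repeats
#' until exactly `K` clusters remain. Cluster means are computed after
#' sign-aligning members to the current mean, then GFP-normalized.
#' Deterministic given the input order; ties break toward the lowest
#' cluster index.
#'
#' @param maps A `peakset` or a maps x channels matrix.
#' @param K Number of clusters to retain.
#' @return List with `mapset` (labels `"1"`..`"K"` until matched), and
#'   `assignment` (cluster index per input map).
#' @export
taahc <- function(maps, K) {
  X <- .gfp_normalize_rows(.as_maps_matrix(maps))
  m <- nrow(X); nch <- ncol(X)
  if (K < 1 || K > m) stop("need 1 <= K <= number of maps")

  members <- as.list(seq_len(m))
  means <- X                      # row i = mean of cluster i
  scores <- rep(1, m)             # summed |corr| of members to mean
  active <- rep(TRUE, m)
  n_active <- m

  recompute <- function(idx) {
    mu <- .polarity_mean(X[members[[idx]], , drop = FALSE], means[idx, ])
    means[idx, ] <<- mu
    scores[idx] <<- sum(abs(X[members[[idx]], , drop = FALSE] %*% mu)) / nch
  }

  while (n_active > K) {
    act <- which(active)
    worst <- act[which.min(scores[act])]
    freed <- sort(members[[worst]])
    active[worst] <- FALSE
    members[worst] <- list(NULL)
    n_active <- n_active - 1
    act <- which(active)
    for (j in freed) {
      cr <- abs(means[act, , drop = FALSE] %*% X[j, ]) / nch
      tgt <- act[which.max(cr)]
      members[[tgt]] <- c(members[[tgt]], j)
      recompute(tgt)
    }
  }

  act <- which(active)
  assignment <- integer(m)
  for (k in seq_along(act)) assignment[members[[act[k]]]] <- k
  out_maps <- means[act, , drop = FALSE]
  rownames(out_maps) <- as.character(seq_along(act))
  ms <- mapset(out_maps, algorithm = "taahc")
  ms$gev_on_source <- gev(maps, ms, assignment)
  list(mapset = ms, assignment = assignment)
}

#' Polarity-invariant (modified) k-means clustering of topographies
#'
#' Each restart seeds K templates with randomly chosen non-identical input
#' maps, then alternates polarity-invariant assignment (highest absolute
#' spatial correlation) with template re-estimation (sign-aligned mean,
#' GFP-normalized) until the global explained variance (GEV) stops
#' improving by more than `tol`. The restart with the highest GEV wins.
#' Reproducible under `seed`.
#'
#' @param maps A `peakset` or maps x channels matrix.
#' @param K Number of templates.
#' @param restarts Number of random restarts (study default 300; smaller
#'   values suit exploratory runs).
#' @param seed Integer seed.
#' @param tol GEV improvement tolerance.
#' @param max_iter Iteration cap per restart.
#' @return List with `mapset`, `assignment`, and `gev`.
#' @export
kmeans_microstates <- function(maps, K, restarts = 300, seed = 1,
                               tol = 1e-7, max_iter = 1000) {
  ps_gfp <- if (inherits(maps, "peakset")) maps$gfp else NULL
  X0 <- .as_maps_matrix(maps)
  X <- .gfp_normalize_rows(X0)
  m <- nrow(X); nch <- ncol(X)
  if (K > m) stop("K exceeds the number of maps")
  w <- if (is.null(ps_gfp)) apply(X0, 1, gfp) else ps_gfp  # GEV weights
  w2sum <- sum(w^2)
  # distinct maps available?
  if (K > 1) {
    ex <- .dedupe_rows(X)
    if (length(ex) < K) stop("fewer than K distinct maps")
  }
  rng <- .new_rng(seed)
  best <- list(gev = -Inf)
  for (r in seq_len(restarts)) {
    sel <- .sample_distinct(X, K, rng)
    Tm <- X[sel, , drop = FALSE]
    prev <- -Inf
    for (it in seq_len(max_iter)) {
      C <- X %*% t(Tm) / nch
      aC <- abs(C)
      a <- max.col(aC, ties.method = "first")
      cur <- sum((w * aC[cbind(seq_len(m), a)])^2) / w2sum
      for (k in seq_len(K)) {
        in_k <- a == k
        if (!any(in_k)) {            # re-seed an empty cluster
          worst <- which.min(apply(aC, 1, max))
          Tm[k, ] <- X[worst, ]
          next
        }
        s <- sign(C[in_k, k]); s[s == 0] <- 1
        Tm[k, ] <- .gfp_normalize_rows(
          matrix(colSums(X[in_k, , drop = FALSE] * s), nrow = 1))[1, ]
      }
      if (cur - prev < tol && it > 1) break
      prev <- cur
    }
    C <- X %*% t(Tm) / nch
    a <- max.col(abs(C), ties.method = "first")
    g <- sum((w * abs(C[cbind(seq_len(m), a)]))^2) / w2sum
    if (g > best$gev) best <- list(gev = g, templates = Tm, assignment = a)
  }
  rownames(best$templates) <- as.character(seq_len(K))
  ms <- mapset(best$templates, algorithm = "kmeans",
               gev_on_source = best$gev)
  list(mapset = ms, assignment = best$assignment, gev = best$gev)
}

# indices of rows that are pairwise non-identical up to polarity
.dedupe_rows <- function(Xn) {
  keep <- integer(0)
  for (i in seq_len(nrow(Xn))) {
    dup <- FALSE
    for (j in keep) {
      if (abs(sum(Xn[i, ] * Xn[j, ]) / ncol(Xn)) > 1 - 1e-12) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
    if (length(keep) >= 64) break   # enough for any sensible K
  }
  keep
}

.sample_distinct <- function(Xn, K, rng, max_tries = 1000) {
  m <- nrow(Xn)
  for (i in seq_len(max_tries)) {
    sel <- rng$sample_k(m, K)
    C <- Xn[sel, , drop = FALSE] %*% t(Xn[sel, , drop = FALSE]) / ncol(Xn)
    if (all(abs(C[upper.tri(C)]) < 1 - 1e-12)) return(sel)
  }
  stop("could not find K non-identical seed maps")
}

#' Global explained variance (GEV)
#'
#' Fraction of GFP-weighted topographic variance explained by assigning
#' each original map to a template:
#' \deqn{GEV = \frac{\sum_j (GFP_j \, C_{j})^2}{\sum_j GFP_j^2}}
#' where \eqn{C_j} is the (polarity-invariant) spatial correlation between
#' map j and its assigned template.
#'
#' @param maps A `peakset` (GFP weights taken from the peaks) or a maps x
#'   channels matrix (weights = each map's own GFP).
#' @param templates A `mapset` or templates x channels matrix.
#' @param assignment Integer template index per map; if `NULL`, each map
#'   is assigned to its best-correlated template.
#' @return Scalar in `[0, 1]`.
#' @export
gev <- function(maps, templates, assignment = NULL) {
  X0 <- .as_maps_matrix(maps)
  w <- if (inherits(maps, "peakset")) maps$gfp else apply(X0, 1, gfp)
  Tm <- if (inherits(templates, "mapset")) templates$maps else
    .gfp_normalize_rows(as.matrix(templates))
  C <- abs(.gfp_normalize_rows(X0) %*% t(Tm)) / ncol(X0)
  if (is.null(assignment)) assignment <- max.col(C, ties.method = "first")
  cj <- C[cbind(seq_len(nrow(C)), assignment)]
  sum((w * cj)^2) / sum(w^2)
}

#' Cross-validation criterion for the number of microstates
#'
#' Predictive-residual criterion trading explained variance against
#' degrees of freedom: \eqn{CV = \hat\sigma^2 ((n-1)/(n-1-K))^2}, where
#' \eqn{\hat\sigma^2} is the mean residual variance of the maps about
#' their assigned (unit-norm) templates and n is the number of
#' electrodes. Offered as a diagnostic; the analysis itself fixes K = 4.
#'
#' @inheritParams gev
#' @return Scalar (same units as map variance).
#' @export
cv_criterion <- function(maps, templates, assignment = NULL) {
  X <- .as_maps_matrix(maps)
  X <- X - rowMeans(X)
  Tm <- if (inherits(templates, "mapset")) templates$maps else
    .gfp_normalize_rows(as.matrix(templates))
  K <- nrow(Tm)
  n <- ncol(X)
  if (K >= n - 1) stop("cv_criterion requires K < n_electrodes - 1")
  Tn <- Tm / sqrt(rowSums(Tm^2))   # unit L2 norm
  C <- X %*% t(Tn)
  if (is.null(assignment)) assignment <- max.col(abs(C), ties.method = "first")
  proj <- C[cbind(seq_len(nrow(X)), assignment)]
  sigma2 <- sum(rowSums(X^2) - proj^2) / (nrow(X) * (n - 1))
  sigma2 * ((n - 1) / (n - 1 - K))^2
}

#' Match map labels against a reference map set
#'
#' Finds the one-to-one pairing of maps to reference maps that maximizes
#' the total absolute spatial correlation (exhaustive search over
#' permutations; ties break in label order), and returns the map set
#' reordered and relabeled with the reference labels.
#'
#' @param ms A `mapset` to relabel.
#' @param reference A `mapset` with the target labels (same montage and
#'   map count).
#' @return Relabeled `mapset`, with attribute `match_correlation` giving
#'   the per-label absolute correlation to the reference.
#' @export
match_labels <- function(ms, reference) {
  A <- ms$maps; B <- reference$maps
  if (nrow(A) != nrow(B)) stop("map sets have different sizes")
  K <- nrow(A)
  C <- abs(A %*% t(B)) / ncol(A)    # rows: ms maps, cols: reference
  perms <- .permutations(K)
  tot <- apply(perms, 1, function(p) sum(C[cbind(p, seq_len(K))]))
  p <- perms[which.max(tot), ]      # p[j] = ms-map paired with reference j
  out <- ms
  out$maps <- A[p, , drop = FALSE]
  rownames(out$maps) <- reference$labels
  out$labels <- reference$labels
  attr(out, "match_correlation") <-
    stats::setNames(C[cbind(p, seq_len(K))], reference$labels)
  out
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Derive microstate maps for a study
#'
#' Two-level clustering over the recordings of a study. First level: the
#' GFP-peak maps of each recording are clustered into K maps. Second
#' level, by strategy: `global` pools all first-level maps (K x
#' n_recordings) and clusters them once; `by_session` pools and clusters
#' within each session; `by_recording` stops after the first level. All
#' resulting map sets are label-matched: against `reference` if given,
#' otherwise against the canonical archetype topographies of the montage
#' (so a global TAAHC result can serve as reference for the other runs,
#' as the analysis design intends).
#'
#' @param peaksets List of `peakset` objects (one per recording).
#' @param strategy `"global"`, `"by_session"` or `"by_recording"`.
#' @param algorithm `"taahc"` or `"kmeans"`.
#' @param K Number of microstate classes (default 4).
#' @param reference Optional `mapset` used for label matching.
#' @param restarts,seed k-means parameters (ignored for TAAHC).
#' @return List of class `derived_maps`: `strategy`, `algorithm`,
#'   `mapsets` — a named list with one `mapset` per fitting unit (key
#'   `"global"`, the session id, or the recording id) — and
#'   `first_level`, the per-recording map sets.
#' @export
derive_maps <- function(peaksets, strategy = c("global", "by_session",
                                               "by_recording"),
                        algorithm = c("taahc", "kmeans"), K = 4,
                        reference = NULL, restarts = 300, seed = 1) {
  strategy <- match.arg(strategy)
  algorithm <- match.arg(algorithm)
  cluster_fun <- function(maps, s) {
    if (algorithm == "taahc") taahc(maps, K)
    else kmeans_microstates(maps, K, restarts = restarts, seed = s)
  }
  rec_ids <- vapply(peaksets, function(p)
    paste(p$subject_id, p$session_id, sep = "_"), "")
  for (i in seq_along(peaksets)) {
    if (nrow(peaksets[[i]]$maps) == 0)
      stop("empty peak set for recording ", rec_ids[i])
  }
  first <- vector("list", length(peaksets))
  for (i in seq_along(peaksets)) {
    res <- cluster_fun(peaksets[[i]], seed + i)
    res$mapset$strategy <- strategy
    colnames(res$mapset$maps) <- peaksets[[i]]$channel_labels
    first[[i]] <- res$mapset
  }
  names(first) <- rec_ids
  if (is.null(reference)) {
    arch <- make_template_maps(peaksets[[1]]$channel_labels, seed = 1,
                               jitter = 0)
    reference <- mapset(arch, algorithm = "archetype", strategy = "canonical")
  }
  pool <- function(sets) do.call(rbind, lapply(sets, `[[`, "maps"))
  finish <- function(res) {
    res$mapset$strategy <- strategy
    match_labels(res$mapset, reference)
  }
  mapsets <- switch(strategy,
    global = {
      res <- cluster_fun(pool(first), seed)
      list(global = finish(res))
    },
    by_session = {
      ses <- vapply(peaksets, `[[`, "", "session_id")
      out <- lapply(split(seq_along(first), ses), function(ii) {
        finish(cluster_fun(pool(first[ii]), seed))
      })
      out
    },
    by_recording = lapply(first, function(ms)
      match_labels(ms, reference))
  )
  structure(list(strategy = strategy, algorithm = algorithm,
                 mapsets = mapsets, first_level = first,
                 K = K),
            class = "derived_maps")
}

#' Serialize a mapset to delimited text
#'
#' Writes the map matrix as a tab-separated table (label then one column
#' per electrode) plus a `# key: value` metadata preamble.
#'
#' @param ms A `mapset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapset <- function(ms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# algorithm: %s", ms$algorithm),
               sprintf("# strategy: %s", ms$strategy),
               sprintf("# gev_on_source: %.6f", ms$gev_on_source)), con)
  tab <- data.frame(label = ms$labels, ms$maps, check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mapset
#' @export
read_mapset <- function(path) {
  meta <- grep("^# ", readLines(path, n = 10), value = TRUE)
  get <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(hit) == 0) NA_character_ else sub(paste0("^# ", key, ": "), "", hit)
  }
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  maps <- as.matrix(tab[, -1, drop = FALSE])
  rownames(maps) <- tab$label
  mapset(maps, labels = tab$label, algorithm = get("algorithm"),
         strategy = get("strategy"),
         gev_on_source = as.numeric(get("gev_on_source")))
}
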
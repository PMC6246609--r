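#' @name stimresp
#' @title Stimulus-responsive genes and expression ordination
#' @description
#' A gene responds to a stimulus when its DNA-normalized mRNA-RPKM changes
#' at least five-fold between the baseline and the post-stimulus condition
#' and the direction-matched expression exceeds 50 RPKM. Community-scale
#' expression dynamics are ordinated by weighted MDS (bins) and weighted
#' canonical correspondence analysis (genes or bins constrained by the
#' operational variables SucEET / SucOC / AcProEET); genes are attributed
#' to stimuli by nearest arrow midpoint in the wCCA plane.
NULL

#' Classify stimulus-responsive genes
#'
#' For every stimulus contrast in the design, computes the response/baseline
#' ratio of normalized mRNA-RPKM (zeros replaced by a small pseudocount
#' before the ratio) and calls: positive iff `after/before >= fold` and
#' `after >= min_rpkm`; negative iff `before/after >= fold` and
#' `before >= min_rpkm` (the RPKM gate is direction-matched). Entries with
#' undefined normalized expression in either condition are skipped and
#' counted in the `n_skipped` attribute.
#'
#' @param expression Expression table ([expression_table()]).
#' @param design Condition design ([default_design()]).
#' @param fold Fold-change threshold (default 5).
#' @param min_rpkm Gating RPKM threshold (default 50).
#' @param pseudocount Replacement for zero RPKM in ratios (default 0.01).
#' @return Tibble `orf_id, stimulus, direction, fold_change, gating_rpkm`
#'   (direction `positive`/`negative`/`none`).
#' @export
responsive_genes <- function(expression, design, fold = 5, min_rpkm = 50,
                             pseudocount = 0.01) {
  validate_design(design)
  wide <- expression |>
    select("orf_id", "condition", "normalized_mrna_rpkm") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "normalized_mrna_rpkm")
  calls <- purrr::map_dfr(seq_len(nrow(design$comparisons)), function(i) {
    cmp <- design$comparisons[i, ]
    before <- wide[[cmp$baseline]]
    after <- wide[[cmp$response]]
    tibble(orf_id = wide$orf_id, stimulus = cmp$stimulus,
           before = before, after = after)
  })
  skipped <- is.na(calls$before) | is.na(calls$after)
  out <- calls |>
    filter(!skipped) |>
    mutate(
      b = pmax(.data$before, pseudocount),
      a = pmax(.data$after, pseudocount),
      ratio = .data$a / .data$b,
      direction = dplyr::case_when(
        .data$ratio >= fold & .data$after >= min_rpkm ~ "positive",
        1 / .data$ratio >= fold & .data$before >= min_rpkm ~ "negative",
        TRUE ~ "none"
      ),
      fold_change = ifelse(.data$direction == "negative",
                           1 / .data$ratio, .data$ratio),
      gating_rpkm = ifelse(.data$direction == "negative",
                           .data$before, .data$after)
    ) |>
    select("orf_id", "stimulus", "direction", "fold_change", "gating_rpkm")
  attr(out, "n_skipped") <- sum(skipped)
  out
}

#' Tally responsive genes by taxon
#'
#' Sums positive/negative calls per stimulus and taxon and overlays the
#' count of responsive multi-heme cytochromes.
#'
#' @param calls Output of [responsive_genes()].
#' @param orf_bins Tibble `orf_id, bin`.
#' @param taxon_map Optional tibble `bin, taxon` (defaults to bin itself).
#' @param cytc Optional cytochrome annotations (`protein_id` matching
#'   orf ids, `cytc_class`).
#' @return Tibble `stimulus, direction, taxon, n, n_mh_cytc`.
#' @export
tally_by_taxon <- function(calls, orf_bins, taxon_map = NULL, cytc = NULL) {
  df <- calls |>
    filter(.data$direction != "none") |>
    left_join(orf_bins, by = "orf_id") |>
    mutate(bin = dplyr::coalesce(.data$bin, UNASSIGNED))
  if (is.null(taxon_map)) {
    df <- df |> mutate(taxon = .data$bin)
  } else {
    df <- df |> left_join(taxon_map, by = "bin") |>
      mutate(taxon = dplyr::coalesce(.data$taxon, .data$bin))
  }
  if (!is.null(cytc)) {
    df <- df |>
      left_join(cytc |> select(orf_id = "protein_id", "cytc_class"),
                by = "orf_id") |>
      mutate(is_mh = dplyr::coalesce(.data$cytc_class == "multi_heme", FALSE))
  } else {
    df <- df |> mutate(is_mh = FALSE)
  }
  df |>
    group_by(.data$stimulus, .data$direction, .data$taxon) |>
    summarise(n = n(), n_mh_cytc = sum(.data$is_mh), .groups = "drop")
}

# ---- weighted MDS -------------------------------------------------------

#' Weighted multidimensional scaling of bin expression profiles
#'
#' Metric least-squares MDS (SMACOF majorization) of the Euclidean
#' distances between per-condition relative expression profiles, with
#' per-point weights (mean mRNA-RPKM of the bin) multiplying the stress
#' contribution of every pair they touch. Initialized from classical
#' scaling, so the fit is deterministic; the seed only perturbs degenerate
#' starts.
#'
#' @param profiles Numeric matrix (bins x conditions), rows are relative
#'   expression profiles; `>= 3` rows required.
#' @param weights Per-bin non-negative weights (default equal).
#' @param dims Embedding dimension (default 2).
#' @param seed Integer seed.
#' @param max_iter,tol Majorization controls.
#' @return A `wmds` object: `points` tibble, `stress` (final weighted raw
#'   stress), `stress_history`, `weights`, `converged`.
#' @export
wmds <- function(profiles, weights = NULL, dims = 2, seed = 1,
                 max_iter = 500, tol = 1e-12) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 3) stop("weighted MDS needs >= 3 points")
  w <- weights %||% rep(1, n)
  stopifnot(length(w) == n, all(w >= 0))
  delta <- as.matrix(dist(profiles))
  W <- outer(w, w)
  diag(W) <- 0
  set.seed(derive_seed(seed, 53))
  Z <- suppressWarnings(cmdscale(delta, k = dims))
  if (ncol(Z) < dims) {
    Z <- cbind(Z, matrix(rnorm(n * (dims - ncol(Z)), sd = 1e-6), n))
  }
  V <- diag(rowSums(W)) - W
  ones <- matrix(1 / n, n, n)
  Vp <- solve(V + ones) - ones
  stress_of <- function(Z) {
    d <- as.matrix(dist(Z))
    sum(W * (d - delta)^2) / 2
  }
  history <- stress_of(Z)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- as.matrix(dist(Z))
    ratio <- ifelse(d > 0, delta / d, 0)
    B <- -W * ratio
    diag(B) <- -rowSums(B)
    Z <- Vp %*% B %*% Z
    s <- stress_of(Z)
    history <- c(history, s)
    prev <- history[length(history) - 1]
    if (prev - s < tol * max(prev, 1e-12)) {
      converged <- TRUE
      break
    }
  }
  pts <- as_tibble(Z, .name_repair = ~ paste0("axis", seq_len(dims)))
  pts <- bind_cols(tibble(point = rownames(profiles) %||%
                            paste0("p", seq_len(n))), pts)
  structure(list(points = pts, stress = history[length(history)],
                 stress_history = history, weights = w,
                 converged = converged),
            class = "wmds")
}

# ---- weighted CCA -------------------------------------------------------

weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  sxy <- sum(w * (x - mx) * (y - my))
  sx <- sqrt(sum(w * (x - mx)^2)); sy <- sqrt(sum(w * (y - my)^2))
  if (sx == 0 || sy == 0) return(0)
  sxy / (sx * sy)
}

#' Weighted canonical correspondence analysis
#'
#' Correspondence-analysis (chi-square) scaling of a non-negative response
#' matrix with row masses multiplied by normalized row weights, and
#' condition (site) scores constrained to linear combinations of the
#' indicator variables: the standardized residual matrix is projected onto
#' the weighted column space of the constraints and decomposed by SVD (the
#' canonical eigenproblem of constrained ordination). Variable arrows are
#' the weighted correlations of the (centered) constraint columns with the
#' constrained axes. Axis signs are fixed by making the largest-magnitude
#' gene loading positive. An indicator set that partitions the conditions
#' carries one redundant column, which is absorbed by the projection; any
#' further rank deficiency is an error naming the collinear columns.
#'
#' @param Y Non-negative matrix, rows = genes (or bins), columns =
#'   conditions; rows with zero total are dropped.
#' @param X Constraint matrix, conditions x variables (indicators or
#'   numeric).
#' @param row_weights Optional non-negative weights per row of `Y`.
#' @return A `wcca` object: `eigenvalues`, `gene_scores`,
#'   `condition_scores`, `arrows`, `inertia` (total/constrained/
#'   unconstrained), `kept` (row ids used).
#' @export
wcca <- function(Y, X, row_weights = NULL) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (any(Y < 0)) stop("Y must be non-negative")
  if (nrow(X) != ncol(Y)) stop("X must have one row per condition")
  rn <- rownames(Y) %||% paste0("g", seq_len(nrow(Y)))
  w <- row_weights %||% rep(1, nrow(Y))
  stopifnot(length(w) == nrow(Y), all(w >= 0))
  keep <- rowSums(Y) > 0 & w > 0
  Y <- Y[keep, , drop = FALSE]
  w <- w[keep]
  rn <- rn[keep]
  Yw <- Y * (w / mean(w))
  P <- Yw / sum(Yw)
  r <- rowSums(P)            # gene masses
  cm <- colSums(P)           # condition masses
  M <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  Qbar <- t(M)               # conditions x genes
  # weighted centering of constraints
  Xc <- sweep(X, 2, colSums(X * cm))
  Xs <- Xc * sqrt(cm)
  qrx <- qr(Xs)
  rank <- qrx$rank
  is_partition <- all(abs(rowSums(X) - 1) < 1e-12) &&
    all(X %in% c(0, 1))
  expected_rank <- if (is_partition) ncol(X) - 1 else ncol(X)
  if (rank < expected_rank) {
    bad <- colnames(X)[qrx$pivot[(rank + 1):ncol(X)]] %||%
      qrx$pivot[(rank + 1):ncol(X)]
    stop("constraint matrix is rank-deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Qx <- qr.Q(qrx)[, seq_len(rank), drop = FALSE]
  Yhat <- Qx %*% crossprod(Qx, Qbar)
  sv <- svd(Yhat)
  pos <- sv$d^2 > 1e-12 * max(sv$d^2, 1e-300)
  naxes <- min(sum(pos), rank)
  d <- sv$d[seq_len(naxes)]
  U <- sv$u[, seq_len(naxes), drop = FALSE]
  V <- sv$v[, seq_len(naxes), drop = FALSE]
  cond_scores <- U / sqrt(cm)                       # LC site scores
  gene_scores <- (V / sqrt(r)) %*% diag(d, naxes)   # scaling 2
  # deterministic axis orientation
  for (a in seq_len(naxes)) {
    top <- which.max(abs(gene_scores[, a]))
    if (gene_scores[top, a] < 0) {
      gene_scores[, a] <- -gene_scores[, a]
      cond_scores[, a] <- -cond_scores[, a]
      U[, a] <- -U[, a]
    }
  }
  arrows <- vapply(seq_len(ncol(X)), function(j) {
    vapply(seq_len(naxes), function(a) {
      weighted_cor(Xc[, j], cond_scores[, a], cm)
    }, numeric(1))
  }, numeric(naxes))
  arrows <- matrix(arrows, nrow = naxes)
  axis_names <- paste0("axis", seq_len(naxes))
  vn <- colnames(X) %||% paste0("v", seq_len(ncol(X)))
  out <- list(
    eigenvalues = d^2,
    gene_scores = bind_cols(tibble(gene = rn),
                            as_tibble(gene_scores,
                                      .name_repair = ~ axis_names)),
    condition_scores = bind_cols(
      tibble(condition = colnames(Y) %||% paste0("c", seq_len(ncol(Y)))),
      as_tibble(cond_scores, .name_repair = ~ axis_names)),
    arrows = bind_cols(tibble(variable = vn),
                       as_tibble(t(arrows), .name_repair = ~ axis_names)),
    inertia = c(total = sum(M^2), constrained = sum(d^2),
                unconstrained = sum((Qbar - Yhat)^2)),
    row_weights = w, kept = rn
  )
  structure(out, class = "wcca")
}

#' Partition genes among stimuli by wCCA arrow midpoints
#'
#' Each gene point (first two axes) beyond `origin_radius` of the origin is
#' assigned to the variable whose arrow midpoint (half the arrow endpoint)
#' is nearest; points inside the radius stay unassigned. Distance ties go
#' to the lexicographically first variable and are flagged.
#'
#' @param ordination A `wcca` object with at least two axes and two arrows.
#' @param origin_radius Radius around the origin left unassigned; default
#'   10% of the maximum gene-point norm.
#' @return Tibble `gene, variable` (NA inside the radius), `tie` flag.
#' @export
partition_by_arrow_midpoints <- function(ordination, origin_radius = NULL) {
  stopifnot(inherits(ordination, "wcca"))
  if (nrow(ordination$arrows) < 2) stop("need >= 2 variable arrows")
  if (!"axis2" %in% names(ordination$gene_scores)) {
    stop("ordination has fewer than two axes")
  }
  pts <- as.matrix(ordination$gene_scores[, c("axis1", "axis2")])
  mids <- as.matrix(ordination$arrows[, c("axis1", "axis2")]) / 2
  vars <- ordination$arrows$variable
  ord <- order(vars)
  mids <- mids[ord, , drop = FALSE]
  vars <- vars[ord]
  norms <- sqrt(rowSums(pts^2))
  r0 <- origin_radius %||% (0.1 * max(norms))
  res <- apply(pts, 1, function(p) {
    d <- sqrt(colSums((t(mids) - p)^2))
    best <- which(d == min(d))
    c(vars[best[1]], length(best) > 1)
  })
  tibble(
    gene = ordination$gene_scores$gene,
    variable = ifelse(norms > r0, res[1, ], NA_character_),
    tie = as.logical(res[2, ]) & norms > r0
  )
}

#' Select highly expressed marker panels
#'
#' Ranks KO groups and c-type cytochrome families by summed normalized
#' mRNA-RPKM across all conditions and returns the top panels (stable
#' sort, ties by label; boundary ties are flagged with a message).
#'
#' @param expression Expression table.
#' @param labels Tibble `orf_id, ko, cytc_family` (NA where unlabelled).
#' @param top_ko,top_cytc Panel sizes (defaults 50 and 15). When fewer
#'   labels exist than requested, all are returned with a message.
#' @return List of tibbles `ko` and `cytc` (`label, total_expression,
#'   rank`).
#' @export
select_marker_genes <- function(expression, labels, top_ko = 50,
                                top_cytc = 15) {
  totals <- function(col) {
    expression |>
      inner_join(labels |> select("orf_id", label = dplyr::all_of(col)),
                 by = "orf_id") |>
      filter(!is.na(.data$label)) |>
      group_by(.data$label) |>
      summarise(total_expression = sum(.data$normalized_mrna_rpkm,
                                       na.rm = TRUE), .groups = "drop") |>
      arrange(dplyr::desc(.data$total_expression), .data$label) |>
      mutate(rank = row_number())
  }
  take <- function(tab, k, what) {
    if (nrow(tab) < k) {
      message("only ", nrow(tab), " ", what, " labels available (requested ",
              k, ")")
      return(tab)
    }
    if (nrow(tab) > k &&
        tab$total_expression[k] == tab$total_expression[k + 1]) {
      message(what, " panel boundary tie at rank ", k,
              "; lexicographic inclusion")
    }
    tab |> filter(.data$rank <= k)
  }
  list(ko = take(totals("ko"), top_ko, "KO"),
       cytc = take(totals("cytc_family"), top_cytc, "cytochrome family"))
}

#' Marker-gene expression heat-map matrix
#'
#' mRNA/DNA expression ratios of marker gene families per condition, with
#' a flag for families whose ratio changes more than `fold_flag`-fold from
#' the baseline condition.
#'
#' @param expression Expression table.
#' @param labels Tibble `orf_id, family` (family = KO or cytochrome family
#'   label).
#' @param baseline Baseline condition (default `"con1"`).
#' @param fold_flag Fold-change flag threshold (default 2).
#' @return Tibble `family, condition, ratio, fold_change, flagged`.
#' @export
marker_heatmap_matrix <- function(expression, labels, baseline = "con1",
                                  fold_flag = 2) {
  df <- expression |>
    inner_join(labels, by = "orf_id") |>
    filter(!is.na(.data$family)) |>
    group_by(.data$family, .data$condition) |>
    summarise(ratio = sum(.data$mrna_rpkm) /
                pmax(sum(.data$dna_rpkm), 1e-12), .groups = "drop")
  base <- df |> filter(.data$condition == baseline) |>
    select("family", base_ratio = "ratio")
  df |>
    left_join(base, by = "family") |>
    mutate(fold_change = .data$ratio / pmax(.data$base_ratio, 1e-12),
           flagged = .data$fold_change > fold_flag |
             .data$fold_change < 1 / fold_flag) |>
    select("family", "condition", "ratio", "fold_change", "flagged")
}
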
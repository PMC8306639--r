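# Synthetic OTU tables with known ground truth: Gaussian copula latent
# correlation -> log-normal abundances -> group effects -> multinomial
# counts at fixed depth.

#' Field-trial sample design
#'
#' The standard two-soil field layout: for each soil, bulk (unplanted) soil,
#' lettuce without amendment and lettuce with procyanidin amendment, each
#' with `replicates` replicate samples. Sample ids follow the BS/L0/LP +
#' soil-initial convention (e.g. `L0M_2` = unamended lettuce, first soil,
#' replicate 2).
#'
#' @param soils character vector of two soil names.
#' @param replicates replicates per condition (default 3).
#' @return data.frame with row names = sample ids and factor columns
#'   `soil`, `plant` (bulk/lettuce), `treatment` (none/procyanidins).
#' @export
fieldTrialDesign <- function(soils = c("Manziat", "Serail"),
                             replicates = 3L) {
  cond <- data.frame(
    code = c("BS", "L0", "LP"),
    plant = c("bulk", "lettuce", "lettuce"),
    treatment = c("none", "none", "procyanidins"),
    stringsAsFactors = FALSE)
  rows <- list()
  for (s in soils) {
    for (i in seq_len(nrow(cond))) {
      for (r in seq_len(replicates)) {
        id <- sprintf("%s%s_%d", cond$code[i], substr(s, 1, 1), r)
        rows[[id]] <- data.frame(soil = s, plant = cond$plant[i],
                                 treatment = cond$treatment[i],
                                 row.names = id)
      }
    }
  }
  out <- do.call(rbind, rows)
  for (j in seq_along(out)) out[[j]] <- factor(out[[j]])
  out
}

#' Specification of a synthetic OTU table
#'
#' Defines the ground truth for [simulateOtuTable()]: table shape,
#' sequencing depth, sample design, planted correlation blocks and hubs,
#' and multiplicative group effects.
#'
#' Correlation structure is planted on the latent Gaussian scale:
#' \itemize{
#'   \item a block `list(otus =, rho =)` sets every pairwise latent
#'     correlation within `otus` to `rho`;
#'   \item a hub `list(hub =, spokes =, rho =)` uses a one-factor model:
#'     hub-spoke correlation `rho`, spoke-spoke correlation `rho^2` (the
#'     one-factor fill keeps the implied matrix positive semi-definite).
#' }
#' OTUs are referenced by integer index into `1:nOtus`. The implied latent
#' correlation matrix is validated for positive semi-definiteness at
#' generation time.
#'
#' @param nOtus number of OTUs.
#' @param depth sequences per sample (multinomial total).
#' @param design data.frame of per-sample factors (row names = sample ids),
#'   e.g. [fieldTrialDesign()]; or `NULL` with `nSamples` for an
#'   unstructured design.
#' @param nSamples number of samples when `design` is `NULL`.
#' @param blocks list of planted correlation blocks (see Details).
#' @param hubs list of planted hubs (see Details).
#' @param groupEffects list of effects, each
#'   `list(factor =, level =, lfc =, fraction =)` (or `otus =` instead of
#'   `fraction`): abundances of the affected OTU subset are multiplied by
#'   `exp(lfc)` in samples at `level` of `factor`.
#' @param mu,sigma log-normal parameters of the base relative abundances
#'   (defaults 0 and 1).
#' @return list of class `"syntheticSpec"`.
#' @seealso [simulateOtuTable()], [presetSpec()]
#' @export
syntheticSpec <- function(nOtus, depth, design = NULL, nSamples = NULL,
                          blocks = list(), hubs = list(),
                          groupEffects = list(), mu = 0, sigma = 1) {
  if (is.null(design)) {
    if (is.null(nSamples))
      stop("supply either 'design' or 'nSamples'", call. = FALSE)
    design <- data.frame(row.names = sprintf("S%02d", seq_len(nSamples)))
  }
  stopifnot(is.data.frame(design), nOtus >= 1, depth >= 1)
  checkIdx <- function(ix, what) {
    if (any(ix < 1 | ix > nOtus | ix != round(ix)))
      stop(sprintf("%s OTU indices must lie in 1..%d", what, nOtus),
           call. = FALSE)
  }
  for (b in blocks) {
    stopifnot(is.list(b), all(c("otus", "rho") %in% names(b)))
    checkIdx(b$otus, "block")
    if (abs(b$rho) >= 1) stop("block rho must lie in (-1, 1)", call. = FALSE)
  }
  for (h in hubs) {
    stopifnot(is.list(h), all(c("hub", "spokes", "rho") %in% names(h)))
    checkIdx(c(h$hub, h$spokes), "hub")
    if (abs(h$rho) >= 1) stop("hub rho must lie in (-1, 1)", call. = FALSE)
  }
  for (e in groupEffects) {
    stopifnot(is.list(e), all(c("factor", "level", "lfc") %in% names(e)))
    if (!e$factor %in% colnames(design))
      stop(sprintf("group effect factor '%s' not in design", e$factor),
           call. = FALSE)
    if (is.null(e$otus) && is.null(e$fraction))
      stop("group effect needs 'otus' or 'fraction'", call. = FALSE)
    if (!is.null(e$otus)) checkIdx(e$otus, "effect")
  }
  structure(list(nOtus = as.integer(nOtus), depth = as.integer(depth),
                 design = design, blocks = blocks, hubs = hubs,
                 groupEffects = groupEffects, mu = mu, sigma = sigma),
            class = "syntheticSpec")
}

#' Preset synthetic specifications
#'
#' Ready-made table shapes:
#' \describe{
#'   \item{`fieldtrial-16S`}{1,600 OTUs, 18 samples (two soils x bulk/L0/LP
#'     x 3 replicates), depth 7,541 — the shape of a rarefied prokaryotic
#'     16S dataset from a two-soil field trial.}
#'   \item{`fieldtrial-ITS`}{430 OTUs, same design, depth 32,983 — the
#'     shape of the companion fungal ITS dataset.}
#'   \item{`mini`}{100 OTUs, 20 unstructured samples, depth 10,000 — the
#'     calibration/recovery simulation size.}
#' }
#'
#' @param name preset name.
#' @param ... overrides passed on to [syntheticSpec()] (e.g. `blocks`,
#'   `hubs`, `groupEffects`).
#' @return list of class `"syntheticSpec"`.
#' @export
presetSpec <- function(name = c("fieldtrial-16S", "fieldtrial-ITS", "mini"),
                       ...) {
  name <- match.arg(name)
  args <- switch(name,
    "fieldtrial-16S" = list(nOtus = 1600L, depth = 7541L,
                            design = fieldTrialDesign()),
    "fieldtrial-ITS" = list(nOtus = 430L, depth = 32983L,
                            design = fieldTrialDesign()),
    "mini" = list(nOtus = 100L, depth = 10000L, nSamples = 20L))
  do.call(syntheticSpec, utils::modifyList(args, list(...)))
}

latentSigma <- function(spec) {
  S <- diag(spec$nOtus)
  for (b in spec$blocks) {
    S[b$otus, b$otus] <- b$rho
  }
  for (h in spec$hubs) {
    S[h$spokes, h$spokes] <- h$rho^2
    S[h$hub, h$spokes] <- h$rho
    S[h$spokes, h$hub] <- h$rho
  }
  diag(S) <- 1
  S
}

#' Generate a synthetic OTU table with ground truth
#'
#' Per sample, a latent multivariate Gaussian vector is drawn with the
#' block/hub correlation matrix, mapped through
#' \eqn{\exp(\mu + \sigma z)} to abundances, multiplied by the group
#' effects, normalized to proportions, and converted to counts with a
#' multinomial draw of size `depth`. Column sums therefore equal `depth`
#' exactly and output is deterministic given `seed`.
#'
#' Note that correlation is planted on the latent scale; the realized
#' Pearson correlation between abundances is attenuated by the exponential
#' map (for \eqn{\sigma = 1}, latent 0.95 realizes about 0.92). The latent
#' matrix is returned in the truth object so recovery thresholds can be set
#' honestly.
#'
#' @param spec a [syntheticSpec()].
#' @param seed integer seed, or `NULL`.
#' @return list with elements:
#'   \describe{
#'     \item{`table`}{the generated count [OtuTable-class];}
#'     \item{`truth`}{list of class `"syntheticTruth"`: `otuIds`,
#'       `trueEdges` (2-column character matrix of planted pairs),
#'       `trueHubs`, `groupEffects` (with realized OTU subsets),
#'       `latentSigma`.}
#'   }
#' @export
simulateOtuTable <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "syntheticSpec"))
  nO <- spec$nOtus
  ids <- sprintf("OTU_%04d", seq_len(nO))
  samples <- rownames(spec$design)
  nS <- length(samples)
  Sigma <- latentSigma(spec)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("implied latent correlation matrix is not positive semi-definite; reduce rho or overlap",
         call. = FALSE)
  CH <- chol(Sigma + diag(1e-10, nO))

  withSeed(seed, {
    effects <- lapply(spec$groupEffects, function(e) {
      if (is.null(e$otus))
        e$otus <- sort(sample.int(nO, round(e$fraction * nO)))
      e
    })
    Z <- matrix(rnorm(nS * nO), nS, nO) %*% CH   # samples x OTUs
    A <- exp(spec$mu + spec$sigma * t(Z))        # OTUs x samples
    for (e in effects) {
      inGroup <- spec$design[[e$factor]] == e$level
      A[e$otus, inGroup] <- A[e$otus, inGroup] * exp(e$lfc)
    }
    counts <- matrix(0L, nO, nS, dimnames = list(ids, samples))
    for (j in seq_len(nS))
      counts[, j] <- rmultinom(1, spec$depth, A[, j] / sum(A[, j]))
  })

  pairs <- list()
  for (b in spec$blocks) {
    ot <- sort(b$otus)
    if (length(ot) >= 2) {
      cmb <- utils::combn(ot, 2)
      pairs[[length(pairs) + 1L]] <- cbind(ids[cmb[1, ]], ids[cmb[2, ]])
    }
  }
  for (h in spec$hubs) {
    a <- pmin(h$hub, h$spokes); b2 <- pmax(h$hub, h$spokes)
    pairs[[length(pairs) + 1L]] <- cbind(ids[a], ids[b2])
  }
  trueEdges <- if (length(pairs)) unique(do.call(rbind, pairs))
               else matrix(character(0), 0, 2)
  colnames(trueEdges) <- c("otu1", "otu2")
  truth <- structure(
    list(otuIds = ids,
         trueEdges = trueEdges,
         trueHubs = ids[vapply(spec$hubs, `[[`, numeric(1), "hub")],
         groupEffects = lapply(effects, function(e) {
           e$otus <- ids[e$otus]; e
         }),
         latentSigma = Sigma),
    class = "syntheticTruth")
  list(table = otuTable(counts), truth = truth)
}

#' Edge and hub recovery against a synthetic ground truth
#'
#' Compares a built network to the planted structure:
#' sensitivity = |found and true| / |true|, false discovery rate
#' = |found not true| / max(1, |found|) (so an empty network scores
#' FDR 0 by convention), and hub hit = whether every planted hub appears
#' among the network's top hubs.
#'
#' @param net a [CoocNetwork-class].
#' @param truth the `truth` element of [simulateOtuTable()].
#' @return list with `sensitivity`, `fdr`, `hubHit`, `nFound`, `nTrue`.
#' @export
evaluateRecovery <- function(net, truth) {
  stopifnot(is(net, "CoocNetwork"), inherits(truth, "syntheticTruth"))
  ed <- networkEdges(net)
  nodes <- unique(c(ed$otu1, ed$otu2))
  if (length(nodes) && !any(nodes %in% truth$otuIds))
    stop("network and truth have disjoint OTU universes", call. = FALSE)
  found <- pairKey(ed$otu1, ed$otu2)
  true <- pairKey(truth$trueEdges[, 1L], truth$trueEdges[, 2L])
  list(sensitivity = if (length(true)) sum(found %in% true) / length(true)
                     else NA_real_,
       fdr = sum(!found %in% true) / max(1L, length(found)),
       hubHit = length(truth$trueHubs) > 0 &&
                all(truth$trueHubs %in% net@topHubs),
       nFound = length(found), nTrue = length(true))
}
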
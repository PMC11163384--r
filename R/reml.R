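# Bivariate multi-kernel REML.
#
# Records are phenotyped individuals; with two disjoint populations every
# individual carries exactly one record, for the trait of its population.
# The record-level covariance is linear in the parameters,
#   V(theta) = sum_k [ s2_a1k G_k o (t=1)(t=1)' + s_a12k G_k o cross
#                      + s2_a2k G_k o (t=2)(t=2)' ] + s2_e1 D1 + s2_e2 D2,
# which AI-REML exploits directly: gradient and average-information are
# closed-form in the projection matrix P.

# Parameter layout: per kernel (v1, c12, v2) for 2 traits or (v) for 1,
# followed by residual variance(s). `free` masks covariances fixed at 0.

.thetaLayout <- function(nKernels, nTraits, kernelNames) {
  if (nTraits == 2) {
    kn <- rep(kernelNames, each = 3)
    nm <- paste0(c("va1_", "ca12_", "va2_"), kn)
    type <- rep(c("v1", "c", "v2"), nKernels)
  } else {
    nm <- paste0("va_", kernelNames)
    type <- rep("v", nKernels)
  }
  nm <- c(nm, if (nTraits == 2) c("ve1", "ve2") else "ve")
  type <- c(type, rep("e", nTraits))
  list(names = nm, type = type, n = length(nm))
}

# Build the list of component matrices V_i (record level, dense).
.varComponents <- function(spec) {
  t1 <- spec@trait == 1L
  K <- length(spec@kernels)
  out <- list()
  if (spec@nTraits == 2) {
    t2 <- !t1
    M11 <- outer(t1, t1); M22 <- outer(t2, t2)
    M12 <- outer(t1, t2); M12 <- M12 | t(M12)
    for (k in seq_len(K)) {
      G <- spec@kernels[[k]]
      out[[length(out) + 1L]] <- G * M11
      out[[length(out) + 1L]] <- G * M12
      out[[length(out) + 1L]] <- G * M22
    }
    out[[length(out) + 1L]] <- diag(as.numeric(t1))
    out[[length(out) + 1L]] <- diag(as.numeric(t2))
  } else {
    for (k in seq_len(K)) out[[length(out) + 1L]] <- spec@kernels[[k]]
    out[[length(out) + 1L]] <- diag(length(spec@y))
  }
  out
}

# Log-likelihood only, via triangular solves (no full inverse): used in
# the step-halving line search. Returns NULL if V or X'V^-1 X is not PD.
.remlLoglikOnly <- function(spec, Vc, theta) {
  n <- length(spec@y)
  V <- matrix(0, n, n)
  for (i in seq_along(Vc)) V <- V + theta[i] * Vc[[i]]
  cholV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cholV)) return(NULL)
  a <- forwardsolve(cholV, cbind(spec@y, spec@X), upper.tri = TRUE,
                    transpose = TRUE)
  ay <- a[, 1]; aX <- a[, -1, drop = FALSE]
  p <- ncol(spec@X)
  if (p == 0) {
    return(-0.5 * (2 * sum(log(diag(cholV))) + sum(ay^2)) -
             n / 2 * log(2 * pi))
  }
  XtViX <- crossprod(aX)
  cholC <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cholC)) return(NULL)
  XtViy <- crossprod(aX, ay)
  u <- forwardsolve(cholC, XtViy, upper.tri = TRUE, transpose = TRUE)
  yPy <- sum(ay^2) - sum(u^2)
  -0.5 * (2 * sum(log(diag(cholV))) + 2 * sum(log(diag(cholC))) + yPy) -
    (n - p) / 2 * log(2 * pi)
}

# Core quantities at theta. Returns NULL if V or X'V^-1 X is not PD.
.remlEval <- function(spec, Vc, theta, needP = FALSE) {
  n <- length(spec@y)
  V <- matrix(0, n, n)
  for (i in seq_along(Vc)) V <- V + theta[i] * Vc[[i]]
  cholV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cholV)) return(NULL)
  Vinv <- chol2inv(cholV)
  B <- Vinv %*% spec@X                      # V^-1 X
  p <- ncol(spec@X)
  XtViX <- crossprod(spec@X, B)
  if (p > 0) {
    cholC <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cholC)) return(NULL)
    Cinv <- chol2inv(cholC)
    logdetC <- 2 * sum(log(diag(cholC)))
  } else {
    Cinv <- XtViX  # 0 x 0
    logdetC <- 0
  }
  Viy <- Vinv %*% spec@y
  beta <- Cinv %*% crossprod(B, spec@y)
  Py <- Viy - B %*% (Cinv %*% crossprod(spec@X, Viy))
  yPy <- sum(spec@y * Py)
  logdetV <- 2 * sum(log(diag(cholV)))
  ll <- -0.5 * (logdetV + logdetC + yPy) - (n - p) / 2 * log(2 * pi)
  out <- list(loglik = ll, Py = as.numeric(Py), Vinv = Vinv, B = B,
              Cinv = Cinv, beta = as.numeric(beta), n = n)
  if (needP) out$P <- Vinv - B %*% tcrossprod(Cinv, B)
  out
}

.applyP <- function(ev, x) {
  as.numeric(ev$Vinv %*% x - ev$B %*% (ev$Cinv %*% crossprod(ev$B, x)))
}

# Gradient and AI matrix over free parameters.
.gradAI <- function(spec, Vc, ev, free) {
  idx <- which(free)
  nf <- length(idx)
  W <- matrix(0, ev$n, nf)   # V_i P y
  tr <- numeric(nf)
  for (a in seq_len(nf)) {
    Vi <- Vc[[idx[a]]]
    W[, a] <- Vi %*% ev$Py
    # tr(P V_i) = tr(V^-1 V_i) - tr(Cinv B' V_i B)
    tr[a] <- sum(ev$Vinv * Vi) - sum(ev$Cinv * crossprod(ev$B, Vi %*% ev$B))
  }
  grad <- -0.5 * (tr - colSums(W * ev$Py))
  PW <- apply(W, 2, function(x) .applyP(ev, x))
  AI <- 0.5 * crossprod(W, PW)
  AI <- (AI + t(AI)) / 2
  list(grad = grad, AI = AI)
}

# EM-REML step (inverse-free, valid for rank-deficient kernels).
.emStep <- function(spec, Vc, ev, theta, layout, free) {
  n <- ev$n
  t1 <- spec@trait == 1L
  theta2 <- theta
  K <- length(spec@kernels)
  if (spec@nTraits == 2) {
    for (k in seq_len(K)) {
      off <- (k - 1) * 3
      M <- matrix(c(theta[off + 1], theta[off + 2],
                    theta[off + 2], theta[off + 3]), 2, 2)
      G <- spec@kernels[[k]]
      s1 <- ev$Py * t1; s2 <- ev$Py * !t1
      s <- cbind(s1, s2)
      cc <- s %*% t(M)                      # c_p = sum_r M[p,r] s_r
      Gc <- G %*% cc
      PG <- ev$P * G
      Tm <- matrix(0, 2, 2)
      Tm[1, 1] <- sum(PG[t1, t1]); Tm[1, 2] <- sum(PG[t1, !t1])
      Tm[2, 1] <- sum(PG[!t1, t1]); Tm[2, 2] <- sum(PG[!t1, !t1])
      S <- crossprod(cc, Gc) + n * M - M %*% Tm %*% M
      Mn <- (S + t(S)) / (2 * n)
      theta2[off + 1] <- Mn[1, 1]
      theta2[off + 2] <- if (free[off + 2]) Mn[1, 2] else 0
      theta2[off + 3] <- Mn[2, 2]
    }
    dP <- diag(ev$P)
    n1 <- sum(t1); n2 <- n - n1
    e1 <- theta[3 * K + 1]; e2 <- theta[3 * K + 2]
    theta2[3 * K + 1] <- e1 + e1^2 / n1 * (sum(ev$Py[t1]^2) - sum(dP[t1]))
    theta2[3 * K + 2] <- e2 + e2^2 / n2 * (sum(ev$Py[!t1]^2) - sum(dP[!t1]))
  } else {
    for (k in seq_len(K)) {
      G <- spec@kernels[[k]]
      v <- theta[k]
      theta2[k] <- v + v^2 / n *
        (sum(ev$Py * (G %*% ev$Py)) - sum(ev$P * G))
    }
    e <- theta[K + 1]
    theta2[K + 1] <- e + e^2 / n * (sum(ev$Py^2) - sum(diag(ev$P)))
  }
  theta2
}

# Transformed optimization space: log for variances, Fisher-z of the
# kernel correlation for covariances. Every psi maps into the PSD cone
# (|r| < 1 via tanh, variances > 0 via exp), so no step can leave it.
# Variance log-parameters are kept in [log(varFloor), log(varCap)].
.psiFromTheta <- function(theta, layout, varFloor, varCap) {
  psi <- theta
  type <- layout$type
  for (i in seq_len(layout$n)) {
    if (type[i] == "c") {
      v1 <- theta[i - 1]; v2 <- theta[i + 1]
      r <- if (v1 > 0 && v2 > 0) theta[i] / sqrt(v1 * v2) else 0
      psi[i] <- atanh(max(min(r, 0.999), -0.999))
    } else {
      psi[i] <- log(max(min(theta[i], varCap), varFloor))
    }
  }
  psi
}

.thetaFromPsi <- function(psi, layout, varFloor, varCap) {
  theta <- psi
  type <- layout$type
  vi <- type != "c"
  theta[vi] <- exp(pmax(pmin(psi[vi], log(varCap)), log(varFloor)))
  for (i in which(type == "c"))
    theta[i] <- sqrt(theta[i - 1] * theta[i + 1]) * tanh(psi[i])
  theta
}

# Jacobian d theta / d psi (rows theta, columns psi).
.psiJacobian <- function(psi, theta, layout) {
  n <- layout$n
  J <- matrix(0, n, n)
  type <- layout$type
  for (i in seq_len(n)) {
    if (type[i] == "c") {
      r <- tanh(psi[i])
      J[i, i - 1] <- theta[i] / 2
      J[i, i + 1] <- theta[i] / 2
      J[i, i] <- sqrt(theta[i - 1] * theta[i + 1]) * (1 - r^2)
    } else {
      J[i, i] <- theta[i]
    }
  }
  J
}

# Reporting clamp: |r| <= 0.999 on the natural scale.
.clampTheta <- function(theta, layout, varFloor) {
  type <- layout$type
  isV <- type %in% c("v", "v1", "v2", "e")
  theta[isV] <- pmax(theta[isV], varFloor)
  for (i in which(type == "c")) {
    bound <- 0.999 * sqrt(theta[i - 1] * theta[i + 1])
    theta[i] <- max(min(theta[i], bound), -bound)
  }
  theta
}

#' Construct a REML model specification
#'
#' Assembles response records, fixed-effect design and record-level kernel
#' matrices from GRMs and a phenotype table. Individuals with a missing
#' trait value contribute no record. With \code{traits = 2} the two
#' populations supply the two traits and the design holds one overall mean
#' per trait; with \code{traits = 1} a single mean is fitted (or one per
#' population if \code{perPopIntercept}).
#'
#' @param grms list of \linkS4class{GRM} objects (the kernels), all covering
#'   the same individuals.
#' @param pheno data.frame with \code{iid}, \code{pop} and the trait column.
#' @param trait name of the trait column (default: third column).
#' @param traits 1 or 2.
#' @param perPopIntercept for \code{traits = 1}: fit one mean per
#'   population (used by the combined-population model).
#' @param intercept set \code{FALSE} for a model with no fixed effects at
#'   all (an empty design matrix), e.g. on pre-centered responses.
#' @return a \linkS4class{ModelSpec}.
#' @export
modelSpec <- function(grms, pheno, trait = names(pheno)[3], traits = 2,
                      perPopIntercept = FALSE, intercept = TRUE) {
  if (is(grms, "GRM")) grms <- list(grms)
  ref <- grms[[1]]
  pheno <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  if (!nrow(pheno)) stop("no phenotype records", call. = FALSE)
  ids <- match(pheno$iid, ref@iid)
  if (anyNA(ids))
    stop("phenotyped individual missing from the GRM", call. = FALSE)
  popLevels <- levels(factor(as.character(ref@pop)))
  popIdx <- match(as.character(pheno$pop), popLevels)
  y <- pheno[[trait]]
  if (traits == 2) {
    if (length(unique(popIdx)) < 2)
      stop("bivariate model requires records from two populations",
           call. = FALSE)
    traitIdx <- as.integer(popIdx)
    X <- cbind(as.numeric(traitIdx == 1L), as.numeric(traitIdx == 2L))
    colnames(X) <- paste0("mu_", popLevels)
  } else {
    traitIdx <- rep(1L, length(y))
    if (perPopIntercept && length(unique(popIdx)) == 2) {
      X <- cbind(as.numeric(popIdx == 1L), as.numeric(popIdx == 2L))
      colnames(X) <- paste0("mu_", popLevels)
    } else {
      X <- matrix(1, length(y), 1, dimnames = list(NULL, "mu"))
    }
  }
  if (!intercept) X <- matrix(numeric(0), length(y), 0)
  kernels <- lapply(grms, function(gr) {
    if (!identical(gr@iid, ref@iid))
      stop("kernels cover different individuals", call. = FALSE)
    unname(gr@values[ids, ids, drop = FALSE])
  })
  kn <- vapply(grms, function(gr) gr@snpSet, character(1))
  if (anyDuplicated(kn)) kn <- make.unique(kn)
  new("ModelSpec", y = as.numeric(y), trait = traitIdx, X = X,
      kernels = kernels, kernelNames = kn, iid = as.character(pheno$iid),
      nTraits = as.integer(traits))
}

#' REML log-likelihood at given variance components
#'
#' Evaluates the restricted log-likelihood
#' \deqn{-\tfrac12\left[\log|V| + \log|X'V^{-1}X| + y'Py\right]
#'   - \tfrac{n-p}{2}\log 2\pi}
#' with \eqn{P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}}. The
#' \eqn{-(n-p)/2 \log 2\pi} constant is included so that values are
#' comparable across implementations using the same convention.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param vc a \linkS4class{VarianceComponents} (or a list with elements
#'   \code{M} and \code{residual}).
#' @return the log-likelihood.
#' @export
remlLogLik <- function(spec, vc) {
  theta <- .vcToTheta(vc, spec)
  Vc <- .varComponents(spec)
  ev <- .remlEval(spec, Vc, theta)
  if (is.null(ev))
    stop("covariance matrix not positive definite at these components",
         call. = FALSE)
  ev$loglik
}

.vcToTheta <- function(vc, spec) {
  M <- if (is(vc, "VarianceComponents")) vc@M else vc$M
  resid <- if (is(vc, "VarianceComponents")) vc@residual else vc$residual
  if (spec@nTraits == 2) {
    theta <- unlist(lapply(M, function(m) c(m[1, 1], m[1, 2], m[2, 2])))
  } else {
    theta <- vapply(M, function(m) m[1, 1], numeric(1))
  }
  c(theta, resid)
}

.thetaToVc <- function(theta, spec, loglik, converged, nIter, AI, freeNames) {
  K <- length(spec@kernels)
  if (spec@nTraits == 2) {
    M <- lapply(seq_len(K), function(k) {
      off <- (k - 1) * 3
      matrix(c(theta[off + 1], theta[off + 2],
               theta[off + 2], theta[off + 3]), 2, 2)
    })
    resid <- theta[3 * K + (1:2)]
  } else {
    M <- lapply(seq_len(K), function(k) matrix(theta[k], 1, 1))
    resid <- theta[K + 1]
  }
  new("VarianceComponents", M = M, residual = resid, loglik = loglik,
      converged = converged, nIter = as.integer(nIter),
      kernelNames = spec@kernelNames, nTraits = spec@nTraits, AI = AI,
      freeNames = freeNames)
}

#' Fit variance components by AI-REML
#'
#' Average-information REML with EM-REML warm-up iterations. Every proposed
#' step (EM or AI) is accepted only if the restricted log-likelihood does
#' not decrease, with step-halving towards the current point otherwise, so
#' the log-likelihood trajectory is monotone. Components are kept in the
#' positive-semidefinite cone by clamping each kernel's correlation to
#' \eqn{[-0.999, 0.999]} and variances to at least \eqn{10^{-8}} times the
#' phenotypic variance. Default initialization splits each population's
#' phenotypic variance equally between total genetic and residual, the
#' genetic part equally across kernels, and starts all covariances at 0.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param init optional starting \linkS4class{VarianceComponents} (or list
#'   with \code{M}, \code{residual}).
#' @param tol convergence tolerance on the log-likelihood increase.
#' @param maxIter iteration cap; non-convergence returns the current fit
#'   with \code{converged = FALSE} and a warning.
#' @param emIter number of EM warm-up iterations.
#' @param constrainZeroCov integer kernel indices whose genetic covariance
#'   is fixed at 0 (for likelihood-ratio tests).
#' @return a \linkS4class{VarianceComponents}.
#' @export
fitREML <- function(spec, init = NULL, tol = 1e-8, maxIter = 200,
                    emIter = 3, constrainZeroCov = integer(0)) {
  n <- length(spec@y)
  if (n <= ncol(spec@X))
    stop("need more records than fixed effects", call. = FALSE)
  K <- length(spec@kernels)
  layout <- .thetaLayout(K, spec@nTraits, spec@kernelNames)
  Vc <- .varComponents(spec)
  varP <- max(vapply(seq_len(spec@nTraits),
                     function(p) var(spec@y[spec@trait == p]), numeric(1)))
  varFloor <- 1e-8 * varP
  free <- rep(TRUE, layout$n)
  if (length(constrainZeroCov) && spec@nTraits == 2)
    free[(constrainZeroCov - 1) * 3 + 2] <- FALSE
  if (is.null(init)) {
    theta <- numeric(layout$n)
    if (spec@nTraits == 2) {
      v1 <- var(spec@y[spec@trait == 1L]); v2 <- var(spec@y[spec@trait == 2L])
      for (k in seq_len(K)) {
        off <- (k - 1) * 3
        theta[off + 1] <- v1 / 2 / K
        theta[off + 3] <- v2 / 2 / K
      }
      theta[3 * K + 1] <- v1 / 2
      theta[3 * K + 2] <- v2 / 2
    } else {
      vy <- var(spec@y)
      theta[seq_len(K)] <- vy / 2 / K
      theta[K + 1] <- vy / 2
    }
  } else {
    theta <- .vcToTheta(init, spec)
  }
  varCap <- 1e4 * varP
  psi <- .psiFromTheta(theta, layout, varFloor, varCap)
  psi[!free] <- 0                      # constrained covariances: z = 0
  theta <- .thetaFromPsi(psi, layout, varFloor, varCap)
  ev <- .remlEval(spec, Vc, theta, needP = TRUE)
  if (is.null(ev))
    stop("initial covariance matrix not positive definite", call. = FALSE)
  converged <- FALSE
  iter <- 0L
  AI <- diag(sum(free))
  smallRuns <- 0L
  # line search in the transformed space: every candidate is in the cone
  tryPsi <- function(psiProp, refLl, maxHalvings = 12) {
    for (h in 0:maxHalvings) {
      candPsi <- psi + (psiProp - psi) / 2^h
      candPsi[!free] <- 0
      cand <- .thetaFromPsi(candPsi, layout, varFloor, varCap)
      ll2 <- .remlLoglikOnly(spec, Vc, cand)
      if (!is.null(ll2) && ll2 >= refLl - 1e-12)
        return(list(ll = ll2, psi = candPsi, theta = cand))
    }
    NULL
  }
  emPsi <- function() {
    .psiFromTheta(.emStep(spec, Vc, ev, theta, layout, free), layout,
                  varFloor, varCap)
  }
  repeat {
    iter <- iter + 1L
    if (iter > maxIter) break
    if (iter <= emIter) {
      acc <- tryPsi(emPsi(), ev$loglik)
    } else {
      ga <- .gradAI(spec, Vc, ev, free)
      AI <- ga$AI
      J <- .psiJacobian(psi, theta, layout)[free, free, drop = FALSE]
      gPsi <- crossprod(J, ga$grad)
      APsi <- crossprod(J, AI %*% J)
      APsi <- (APsi + t(APsi)) / 2
      # AI proposal, escalating Levenberg damping on failure, then EM
      acc <- NULL
      scale <- mean(abs(diag(APsi))) + 1e-300
      for (lambda in c(0, 1e-6, 1e-3, 1e-1, 1, 10) * scale) {
        step <- tryCatch(solve(APsi + diag(lambda + 1e-12, nrow(APsi)),
                               gPsi),
                         error = function(e) NULL)
        if (is.null(step)) next
        step <- pmax(pmin(step, 3), -3)  # cap the transformed step
        prop <- psi
        prop[free] <- psi[free] + step
        acc <- tryPsi(prop, ev$loglik,
                      maxHalvings = if (lambda == 0) 12 else 4)
        if (!is.null(acc) && acc$ll > ev$loglik + tol) break
      }
      if (is.null(acc)) acc <- tryPsi(emPsi(), ev$loglik)
    }
    if (is.null(acc)) break  # no improving step found: stalled at optimum
    dll <- acc$ll - ev$loglik
    psi <- acc$psi
    theta <- acc$theta
    ev <- .remlEval(spec, Vc, theta, needP = TRUE)
    smallRuns <- if (dll < tol) smallRuns + 1L else 0L
    if (iter > emIter && dll < tol) {
      if (smallRuns >= 3L) {  # persistent micro-steps: at the optimum
        converged <- TRUE
        break
      }
      # confirm with one EM probe: guards against a stalled AI micro-step
      probe <- emPsi()
      probe[!free] <- 0
      pll <- .remlLoglikOnly(spec, Vc,
                             .thetaFromPsi(probe, layout, varFloor, varCap))
      if (!is.null(pll) && pll > ev$loglik + max(tol, 1e-8)) {
        psi <- probe
        theta <- .thetaFromPsi(psi, layout, varFloor, varCap)
        ev <- .remlEval(spec, Vc, theta, needP = TRUE)
      } else {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged && iter > maxIter)
    warning("REML did not converge in ", maxIter, " iterations",
            call. = FALSE)
  if (!converged && iter <= maxIter) converged <- TRUE  # stalled at optimum
  ga <- .gradAI(spec, Vc, ev, free)
  theta <- .clampTheta(theta, layout, varFloor)
  .thetaToVc(theta, spec, ev$loglik, converged, iter, ga$AI,
             layout$names[free])
}

#' Heritabilities, genetic correlations and standard errors
#'
#' From fitted variance components: per-population heritability over the
#' kernel sum, \eqn{h^2_p = \sum_k \sigma^2_{a_p,k} / (\sum_k
#' \sigma^2_{a_p,k} + \sigma^2_{e_p})}, and per-kernel genetic correlation
#' \eqn{r_{g,k} = \sigma_{a12,k} / \sqrt{\sigma^2_{a1,k}\sigma^2_{a2,k}}}.
#' Standard errors come from the inverse average-information matrix by the
#' delta method. A kernel with (near-)zero genetic variance in either
#' population has an undefined correlation, returned as \code{NA}.
#'
#' @param vc a \linkS4class{VarianceComponents} from [fitREML()].
#' @return list with \code{h2} (per population, with SEs) and \code{rg}
#'   (per kernel, with SEs).
#' @export
deriveParams <- function(vc) {
  t <- vc@nTraits
  K <- length(vc@M)
  theta <- if (t == 2) {
    c(unlist(lapply(vc@M, function(m) c(m[1, 1], m[1, 2], m[2, 2]))),
      vc@residual)
  } else {
    c(vapply(vc@M, function(m) m[1, 1], numeric(1)), vc@residual)
  }
  nmAll <- .thetaLayout(K, t, vc@kernelNames)$names
  freeIdx <- match(vc@freeNames, nmAll)
  covTheta <- matrix(0, length(theta), length(theta))
  Vfree <- tryCatch(solve(vc@AI), error = function(e)
    matrix(NA_real_, length(freeIdx), length(freeIdx)))
  covTheta[freeIdx, freeIdx] <- Vfree
  h2fun <- function(th, p) {
    if (t == 2) {
      va <- sum(th[3 * (seq_len(K) - 1) + (2 * p - 1)])
      ve <- th[3 * K + p]
    } else {
      va <- sum(th[seq_len(K)]); ve <- th[K + 1]
    }
    va / (va + ve)
  }
  se <- function(f) {
    gr <- numeric(length(theta))
    for (i in seq_along(theta)) {
      d <- max(abs(theta[i]) * 1e-5, 1e-10)
      tp <- theta; tp[i] <- tp[i] + d
      tm <- theta; tm[i] <- tm[i] - d
      gr[i] <- (f(tp) - f(tm)) / (2 * d)
    }
    sqrt(max(0, t(gr) %*% covTheta %*% gr))
  }
  h2 <- data.frame(population = seq_len(t),
                   h2 = vapply(seq_len(t), function(p) h2fun(theta, p),
                               numeric(1)),
                   se = vapply(seq_len(t),
                               function(p) se(function(th) h2fun(th, p)),
                               numeric(1)))
  rg <- NULL
  if (t == 2) {
    rgfun <- function(th, k) {
      off <- (k - 1) * 3
      th[off + 2] / sqrt(th[off + 1] * th[off + 3])
    }
    tiny <- 1e-6 * max(theta)
    rg <- data.frame(
      kernel = vc@kernelNames,
      rg = vapply(seq_len(K), function(k) {
        off <- (k - 1) * 3
        if (theta[off + 1] <= tiny || theta[off + 3] <= tiny)
          return(NA_real_)
        rgfun(theta, k)
      }, numeric(1)),
      se = vapply(seq_len(K), function(k) {
        off <- (k - 1) * 3
        if (theta[off + 1] <= tiny || theta[off + 3] <= tiny)
          return(NA_real_)
        se(function(th) rgfun(th, k))
      }, numeric(1)))
  }
  list(h2 = h2, rg = rg)
}

#' Likelihood-ratio test for zero genetic covariance in one kernel
#'
#' Refits the model with the chosen kernel's genetic covariance fixed at 0
#' and compares restricted log-likelihoods: the statistic
#' \eqn{2(\ell_{full} - \ell_0)} (clamped at 0) is referred to a 1-df
#' chi-square.
#'
#' @param spec a \linkS4class{ModelSpec} with 2 traits.
#' @param kernelIndex which kernel's covariance to test.
#' @param full optional pre-computed unconstrained fit.
#' @param ... passed to [fitREML()].
#' @return list with \code{statistic}, \code{p}, \code{full}, \code{null}.
#' @export
lrtZeroCovariance <- function(spec, kernelIndex = 1, full = NULL, ...) {
  if (spec@nTraits != 2)
    stop("covariance test requires a bivariate model", call. = FALSE)
  null <- fitREML(spec, constrainZeroCov = kernelIndex, ...)
  if (is.null(full)) full <- fitREML(spec, ...)
  if (full@loglik < null@loglik) {
    # restart the unconstrained fit from the constrained optimum (a valid
    # interior point of the larger parameter space)
    full2 <- fitREML(spec, init = null, ...)
    if (full2@loglik > full@loglik) full <- full2
  }
  if (null@loglik > full@loglik + 1e-6)
    stop("optimizer failure: constrained log-likelihood exceeds ",
         "unconstrained", call. = FALSE)
  stat <- max(0, 2 * (full@loglik - null@loglik))
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       full = full, null = null)
}

#' Fit report table
#'
#' One row per kernel with variance components, genetic correlation, SEs
#' and the fit's log-likelihood and convergence flag.
#'
#' @param vc a \linkS4class{VarianceComponents}.
#' @return a data.frame.
#' @export
fitReport <- function(vc) {
  dp <- deriveParams(vc)
  K <- length(vc@M)
  if (vc@nTraits == 2) {
    df <- data.frame(
      kernel = vc@kernelNames,
      s2_a1 = vapply(vc@M, function(m) m[1, 1], numeric(1)),
      s_a12 = vapply(vc@M, function(m) m[1, 2], numeric(1)),
      s2_a2 = vapply(vc@M, function(m) m[2, 2], numeric(1)),
      rg = dp$rg$rg, rg_se = dp$rg$se)
  } else {
    df <- data.frame(kernel = vc@kernelNames,
                     s2_a = vapply(vc@M, function(m) m[1, 1], numeric(1)))
  }
  df$loglik <- vc@loglik
  df$converged <- vc@converged
  df
}
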
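#' PCA of environmental covariables
#'
#' Centers and scales the population x covariable matrix, removes constant
#' columns (with a warning), and decomposes it into orthonormal loadings and
#' scores. The number of retained PCs is either given directly or chosen as
#' the smallest number whose cumulative variance explained reaches
#' \code{varThreshold}.
#'
#' @param covariates population x covariable numeric matrix (rownames =
#'   populations).
#' @param nKeep number of PCs to retain (default 7).
#' @param varThreshold when non-NULL, retain the smallest number of PCs
#'   explaining at least this proportion of variance (overrides
#'   \code{nKeep}).
#' @return an \linkS4class{EnvDesign}.
#' @export
envPCA <- function(covariates, nKeep = 7, varThreshold = NULL) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) < 2) stop("need at least two populations")
    sds <- apply(covariates, 2, stats::sd)
    if (any(sds == 0)) {
        warning("dropping constant covariate column(s): ",
                paste(colnames(covariates)[sds == 0], collapse = ", "))
        covariates <- covariates[, sds > 0, drop = FALSE]
    }
    ctr <- colMeans(covariates)
    scl <- apply(covariates, 2, stats::sd)
    xs <- scale(covariates, center = ctr, scale = scl)
    sv <- svd(xs)
    varExp <- sv$d^2 / sum(sv$d^2)
    scores <- sv$u %*% diag(sv$d, length(sv$d))
    dimnames(scores) <- list(rownames(covariates),
                             paste0("PC", seq_along(sv$d)))
    loadings <- sv$v
    dimnames(loadings) <- list(colnames(covariates), colnames(scores))
    if (!is.null(varThreshold))
        nKeep <- which(cumsum(varExp) >= varThreshold)[1]
    nKeep <- min(nKeep, ncol(scores))
    new("EnvDesign", covariates = covariates, center = ctr, scale = scl,
        loadings = loadings, scores = scores, varExplained = varExp,
        nKeep = nKeep, B = NULL, freq = NULL, truth = list())
}

#' Project new locations onto the environmental PCs
#'
#' Applies the training centering, scaling and loadings to new covariate
#' rows; applied to a training row it reproduces that row's score.
#'
#' @param design an \linkS4class{EnvDesign}.
#' @param newCov matrix/data.frame with the design's covariate columns.
#' @return matrix of scores on the retained PCs.
#' @export
projectEnv <- function(design, newCov) {
    newCov <- as.matrix(newCov[, colnames(design@covariates), drop = FALSE])
    xs <- scale(newCov, center = design@center, scale = design@scale)
    xs %*% design@loadings[, seq_len(design@nKeep), drop = FALSE]
}

#' Estimate gene-environment association coefficients
#'
#' Per-SNP linear regression of population allele frequencies on the
#' retained environmental PC scores (with intercept), optionally ridge
#' penalized; the coefficient matrix B (SNP x PC) feeds the genetic-offset
#' metric. This linear estimator treats populations as adapted to their
#' environment of origin; it is a deliberately simple estimator of the
#' environmental effects on allele frequencies whose accuracy is assessed by
#' recovery of simulated truth.
#'
#' @param design an \linkS4class{EnvDesign} with \code{freq} set, or NULL if
#'   \code{freq}/\code{scores} given directly.
#' @param freq SNP x population allele-frequency matrix (defaults to
#'   \code{design@freq}).
#' @param ridge ridge penalty on the PC coefficients (0 = OLS). Forced to a
#'   small positive value, with a warning, when the score design is
#'   collinear.
#' @return the design with slot \code{B} filled (or the B matrix when
#'   \code{design} is NULL).
#' @export
estimateGeaCoefficients <- function(design, freq = NULL, ridge = 0) {
    scores <- envScores(design)
    if (is.null(freq)) freq <- design@freq
    if (is.null(freq)) stop("no allele frequencies supplied")
    if (nrow(scores) < ncol(scores) + 2)
        stop("need at least nPCs + 2 populations")
    X <- cbind(1, scores)
    XtX <- crossprod(X)
    pen <- diag(c(0, rep(1, ncol(scores))))
    if (ridge == 0 && rcond(XtX) < 1e-10) {
        warning("collinear PC scores; ridge penalty forced on")
        ridge <- 1e-6
    }
    coef <- solve(XtX + ridge * pen, t(X) %*% t(freq))
    B <- t(coef[-1, , drop = FALSE])
    dimnames(B) <- list(rownames(freq), colnames(scores))
    design@B <- B
    validObject(design)
    design
}

#' Genetic offset between two environments
#'
#' \deqn{GO = \frac{1}{n_{snp}} (e_j - e_{ref})' B'B (e_j - e_{ref})}
#' a non-negative quadratic distance between environmental PC vectors,
#' weighted by the gene-environment association coefficients; it is
#' symmetric in its two environments and zero iff B(e_j - e_ref) = 0.
#'
#' @param B SNP x PC coefficient matrix.
#' @param ej,eref environmental PC score vectors.
#' @return scalar GO.
#' @examples
#' geneticOffset(matrix(c(1, 0, 0, 2), 2), c(1, 1), c(0, 0))  # 2.5
#' @export
geneticOffset <- function(B, ej, eref) {
    d <- as.numeric(ej) - as.numeric(eref)
    if (length(d) != ncol(B)) stop("PC dimension mismatch between B and scores")
    sum((B %*% d)^2) / nrow(B)
}

#' Unweighted environmental distance
#'
#' \deqn{\delta = \sqrt{(1/n_e)\,\|e_j - e_{ref}\|^2}} the Euclidean
#' distance between environmental PC vectors scaled by the number of PCs.
#'
#' @param ej,eref environmental PC score vectors.
#' @return scalar distance.
#' @export
environmentalDistance <- function(ej, eref) {
    d <- as.numeric(ej) - as.numeric(eref)
    sqrt(mean(d^2))
}

#' Genetic-offset surface over a covariate grid
#'
#' Projects each grid cell's covariates with the training PCA, computes GO
#' to the reference environment per cell, and returns a plain table. Cells
#' with missing covariates are skipped and counted.
#'
#' @param grid data.frame with columns \code{lon}, \code{lat} and the
#'   design's covariate columns.
#' @param design an \linkS4class{EnvDesign} with \code{B} fitted.
#' @param eref reference PC score vector (e.g. the target population's).
#' @return data.frame (cell, lon, lat, go) with attribute
#'   \code{skipped} = number of dropped cells.
#' @export
goSurface <- function(grid, design, eref) {
    if (is.null(design@B)) stop("fit GEA coefficients first")
    covCols <- colnames(design@covariates)
    ok <- stats::complete.cases(grid[, covCols, drop = FALSE])
    sc <- projectEnv(design, grid[ok, , drop = FALSE])
    go <- apply(sc, 1, function(e) geneticOffset(design@B, e, eref))
    out <- data.frame(cell = which(ok), lon = grid$lon[ok],
                      lat = grid$lat[ok], go = go, row.names = NULL)
    attr(out, "skipped") <- sum(!ok)
    out
}
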
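# Independent brute-force re-implementation of the posterior score, written
# as plain double loops over the model slots. Used as the oracle against the
# package's compiled scoring path; kept deliberately naive.

oracleScore <- function(model, xls, psiPar, d0 = 20, alpha = 0.3, kEv = 1,
                        kC = 1, dConn = 4) {
  co <- model@coords
  n <- nrow(co)
  radii <- model@radii
  comp <- model@component
  res <- model@residue
  body <- model@bodyId

  dij <- function(i, j) sqrt(sum((co[i, ] - co[j, ])^2))

  ev <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (body[i] > 0 && body[i] == body[j]) next
    if (comp[i] == comp[j] && abs(res[i] - res[j]) == 1) next
    overlap <- radii[i] + radii[j] - dij(i, j)
    if (overlap > 0) ev <- ev + kEv * overlap^2
  }

  conn <- 0
  for (i in seq_len(n)) {
    j <- which(comp == comp[i] & res == res[i] + 1L)
    if (!length(j)) next
    if (body[i] > 0 && body[i] == body[j]) next
    stretch <- dij(i, j) - dConn
    if (stretch > 0) conn <- conn + kC * stretch^2
  }

  xl <- 0
  if (!is.null(xls) && length(xls) > 0) {
    df <- crossLinks(xls)
    psis <- psiValues(psiPar)
    for (k in seq_len(nrow(df))) {
      i <- which(comp == df$protein1[k] & res == df$residue1[k])
      j <- which(comp == df$protein2[k] & res == df$residue2[k])
      cls <- if (df$linker[k] %in% names(psis)) df$linker[k] else "global"
      d0k <- if (length(d0) == 1 && is.null(names(d0))) d0
        else if (df$linker[k] %in% names(d0)) d0[[df$linker[k]]]
        else d0[["default"]]
      f <- 1 / (1 + exp(alpha * (dij(i, j) - d0k)))
      p <- psis[[cls]] + (1 - 2 * psis[[cls]]) * f
      xl <- xl - log(p)
    }
  }
  c(xl = xl, ev = ev, conn = conn, total = xl + ev + conn)
}

# small free-floating test model: nBodies compact bodies of bodySize beads
# plus a flexible tail, built directly through the class constructor
makeTinyModel <- function(nBodies = 2, bodySize = 5, nFlex = 3, spacing = 8) {
  n <- nBodies * bodySize + nFlex
  coords <- matrix(0, n, 3)
  bodyId <- integer(n)
  bodies <- list()
  k <- 0
  for (b in seq_len(nBodies)) {
    for (i in seq_len(bodySize)) {
      k <- k + 1
      coords[k, ] <- c((b - 1) * spacing + 0.5 * i, 1.9 * i %% 5, 3.8 * i)
      bodyId[k] <- b
    }
    bodies[[b]] <- list(name = paste0("b", b),
                        beads = (b - 1) * bodySize + seq_len(bodySize),
                        rotation = diag(3), translation = c(0, 0, 0))
  }
  segments <- list()
  if (nFlex > 0) {
    for (i in seq_len(nFlex)) {
      k <- k + 1
      coords[k, ] <- c(nBodies * spacing + 3.8 * i, 0, 0)
    }
    segments <- list(list(name = "tail",
                          beads = nBodies * bodySize + seq_len(nFlex)))
    bodyId[nBodies * bodySize + seq_len(nFlex)] <- 0L
  }
  new("SystemModel", coords = coords, radii = rep(3, n),
      component = rep("p", n), residue = seq_len(n),
      bodyId = bodyId, bodies = bodies, segments = segments)
}

# random rigid shuffle of every body plus jitter of flexible beads
randomizeTinyModel <- function(model, transSd = 6) {
  for (b in bodyNames(model)) {
    model <- applyTransform(model, b, randomRotation(),
                            rnorm(3, 0, transSd))
  }
  flex <- which(model@bodyId == 0L)
  model@coords[flex, ] <- model@coords[flex, ] + matrix(rnorm(3 * length(flex), 0, 2),
                                                        length(flex), 3)
  model
}

# canonical 4-row cross-link CSV used by the parser tests
writeXlFixture <- function(path, rows = NULL) {
  if (is.null(rows))
    rows <- data.frame(protein1 = "A", residue1 = c(10, 20, 30, 40),
                       protein2 = c("A", "A", "B", "B"),
                       residue2 = c(50, 60, 5, 15),
                       linker = c("DSS", "DSS", "DSG", "DSS"),
                       id_score = c(35, 31, 29, 40),
                       delta_s = c(0.5, 0.2, 0.8, 0.4),
                       fdr = c(0.01, 0.02, 0.03, 0.001))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}
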
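# Composite physicochemical descriptor set: amino-acid composition,
# Moreau-Broto / Moran / Geary autocorrelations, composition-transition-
# distribution (CTD), sequence-order-coupling numbers, quasi-sequence-order
# descriptors and type-I pseudo-amino-acid composition.

# Three-class residue groupings for the seven CTD properties
# (Dubchak et al. 1995 and follow-up work; the standard published sets).
CTD_GROUPS <- list(
  hydrophobicity = list(polar = c("R","K","E","D","Q","N"),
                        neutral = c("G","A","S","T","P","H","Y"),
                        hydrophobic = c("C","L","V","I","M","F","W")),
  vdw_volume = list(small = c("G","A","S","C","T","P","D"),
                    medium = c("N","V","E","Q","I","L"),
                    large = c("M","H","K","F","R","Y","W")),
  polarity = list(low = c("L","I","F","W","C","M","V","Y"),
                  medium = c("P","A","T","G","S"),
                  high = c("H","Q","R","K","N","E","D")),
  polarizability = list(low = c("G","A","S","D","T"),
                        medium = c("C","P","N","V","E","Q","I","L"),
                        high = c("K","M","H","F","R","Y","W")),
  charge = list(positive = c("K","R"),
                neutral = c("A","N","C","Q","G","H","I","L","M","F","P","S","T","W","Y","V"),
                negative = c("D","E")),
  secondary_structure = list(helix = c("E","A","L","M","Q","K","R","H"),
                             strand = c("V","I","Y","C","W","F","T"),
                             coil = c("G","N","P","S","D")),
  solvent_accessibility = list(buried = c("A","L","F","C","G","I","V","W"),
                               exposed = c("R","K","Q","E","N","D"),
                               intermediate = c("M","S","P","T","H","Y"))
)

# Properties used by the autocorrelation descriptors.
AUTOCORR_PROPERTIES <- c("hydrophobicity", "flexibility", "polarizability",
                         "free_energy", "residue_asa", "residue_volume",
                         "steric", "mutability")

# Standardize a 20-value scale to zero mean, unit (population) sd.
std_scale <- function(p) {
  p <- p[AMINO_ACIDS]
  (p - mean(p)) / sqrt(mean((p - mean(p))^2))
}

# Physicochemical distance matrix used by the sequence-order descriptors:
# root-mean-square difference across the standardized autocorrelation scales.
physchem_distance <- function() {
  if (is.null(.pkg_cache$physchem_dist)) {
    scales <- vapply(AUTOCORR_PROPERTIES, function(nm) std_scale(AA_SCALES[[nm]]),
                     numeric(20L))
    d <- as.matrix(stats::dist(scales)) / sqrt(ncol(scales))
    dimnames(d) <- list(AMINO_ACIDS, AMINO_ACIDS)
    .pkg_cache$physchem_dist <- d
  }
  .pkg_cache$physchem_dist
}

#' Configuration of the composite descriptor set
#'
#' @param families Descriptor families to include, in registry order.
#' @param max_lag Maximum lag for autocorrelation and sequence-order
#'   descriptors (default 30).
#' @param properties Physicochemical scales for the autocorrelations
#'   (default: the eight standard scales).
#' @param qso_weight Weighting factor of the quasi-sequence-order
#'   descriptors (default 0.1).
#' @param pseaac_lambda,pseaac_weight Tier count and weight of the type-I
#'   pseudo-amino-acid composition (defaults 30 and 0.05).
#' @return A list of class `composite_config`.
#' @export
composite_config <- function(families = c("aac", "moreau_broto", "moran", "geary",
                                          "ctd", "socn", "qso", "pseaac"),
                             max_lag = 30L,
                             properties = AUTOCORR_PROPERTIES,
                             qso_weight = 0.1,
                             pseaac_lambda = 30L,
                             pseaac_weight = 0.05) {
  families <- match.arg(families, several.ok = TRUE)
  stopifnot(max_lag >= 1L, pseaac_lambda >= 1L, qso_weight > 0, pseaac_weight > 0)
  bad <- setdiff(properties, names(AA_SCALES))
  if (length(bad)) abort(sprintf("Unknown property scale(s): %s", paste(bad, collapse = ", ")))
  structure(list(families = families, max_lag = as.integer(max_lag),
                 properties = properties, qso_weight = qso_weight,
                 pseaac_lambda = as.integer(pseaac_lambda),
                 pseaac_weight = pseaac_weight),
            class = "composite_config")
}

#' Dimension registry of the composite descriptor set
#'
#' @param config A [composite_config()].
#' @return Named integer vector: dimension contributed by each family.
#' @export
composite_dimensions <- function(config = composite_config()) {
  np <- length(config$properties)
  dims <- c(aac = 20L,
            moreau_broto = np * config$max_lag,
            moran = np * config$max_lag,
            geary = np * config$max_lag,
            ctd = 7L * (3L + 3L + 15L),
            socn = config$max_lag,
            qso = 20L + config$max_lag,
            pseaac = 20L + config$pseaac_lambda)
  dims[config$families]
}

# --- family implementations (one chain) -------------------------------------

comp_aac <- function(ch) {
  as.numeric(table(factor(ch, levels = AMINO_ACIDS))) / length(ch)
}

# Autocorrelations for one standardized property vector p over residues.
# Lags beyond length(p) - 1 are zero-padded so the dimension is constant.
autocorr_one <- function(p, max_lag, kind) {
  n <- length(p)
  out <- numeric(max_lag)
  pbar <- mean(p)
  varn <- mean((p - pbar)^2)        # 1/N sum (p - pbar)^2
  vard <- sum((p - pbar)^2) / (n - 1)
  for (d in seq_len(min(max_lag, n - 1L))) {
    i <- seq_len(n - d)
    out[d] <- switch(kind,
      moreau_broto = sum(p[i] * p[i + d]) / (n - d),
      moran = if (varn > 0) (sum((p[i] - pbar) * (p[i + d] - pbar)) / (n - d)) / varn else 0,
      geary = if (vard > 0) (sum((p[i] - p[i + d])^2) / (2 * (n - d))) / vard else 0
    )
  }
  out
}

comp_autocorr <- function(ch, config, kind) {
  unlist(lapply(config$properties, function(nm) {
    p <- std_scale(AA_SCALES[[nm]])[ch]
    autocorr_one(p, config$max_lag, kind)
  }), use.names = FALSE)
}

comp_ctd_one <- function(ch, groups) {
  n <- length(ch)
  cls <- integer(n)
  for (g in 1:3) cls[ch %in% groups[[g]]] <- g
  comp <- as.numeric(table(factor(cls, levels = 1:3))) / n
  # transitions between distinct classes, unordered pairs (1,2) (1,3) (2,3)
  if (n > 1) {
    a <- cls[-n]; b <- cls[-1]
    pair <- function(x, y) sum((a == x & b == y) | (a == y & b == x))
    trans <- c(pair(1, 2), pair(1, 3), pair(2, 3)) / (n - 1)
  } else {
    trans <- c(0, 0, 0)
  }
  # distribution: relative positions (%) of the first, 25%, 50%, 75% and
  # last occurrence of each class
  distr <- unlist(lapply(1:3, function(g) {
    pos <- which(cls == g)
    if (!length(pos)) return(numeric(5))
    k <- length(pos)
    q <- pos[pmax(1L, c(1L, ceiling(k * 0.25), ceiling(k * 0.5), ceiling(k * 0.75), k))]
    100 * q / n
  }))
  c(comp, trans, distr)
}

comp_ctd <- function(ch) {
  unlist(lapply(CTD_GROUPS, function(g) comp_ctd_one(ch, g)), use.names = FALSE)
}

# Sequence-order-coupling numbers tau_d, zero-padded past |s| - 1.
socn_values <- function(ch, max_lag) {
  d <- physchem_distance()
  n <- length(ch)
  tau <- numeric(max_lag)
  for (lag in seq_len(min(max_lag, n - 1L))) {
    i <- seq_len(n - lag)
    tau[lag] <- sum(d[cbind(ch[i], ch[i + lag])]^2)
  }
  tau
}

comp_qso <- function(ch, config) {
  tau <- socn_values(ch, config$max_lag)
  f <- as.numeric(table(factor(ch, levels = AMINO_ACIDS)))
  denom <- sum(f) + config$qso_weight * sum(tau)
  c(f / denom, config$qso_weight * tau / denom)
}

# Correlation function of type-I pseudo-amino-acid composition: mean squared
# difference of standardized hydropathy, hydrophilicity and side-chain mass.
pseaac_theta <- function(ch, lambda) {
  side_mass <- RESIDUE_MASS - RESIDUE_MASS["G"] + 1.008
  props <- cbind(std_scale(AA_SCALES$hydropathy),
                 std_scale(AA_SCALES$hydrophilicity),
                 std_scale(side_mass))
  rownames(props) <- AMINO_ACIDS
  n <- length(ch)
  theta <- numeric(lambda)
  for (j in seq_len(min(lambda, n - 1L))) {
    i <- seq_len(n - j)
    theta[j] <- mean(rowMeans((props[ch[i + j], , drop = FALSE] -
                               props[ch[i], , drop = FALSE])^2))
  }
  theta
}

comp_pseaac <- function(ch, config) {
  theta <- pseaac_theta(ch, config$pseaac_lambda)
  f <- as.numeric(table(factor(ch, levels = AMINO_ACIDS))) / length(ch)
  denom <- sum(f) + config$pseaac_weight * sum(theta)
  c(f / denom, config$pseaac_weight * theta / denom)
}

composite_one <- function(s, config) {
  ch <- seq_chars(s)
  parts <- lapply(config$families, function(fam) {
    switch(fam,
      aac = comp_aac(ch),
      moreau_broto = comp_autocorr(ch, config, "moreau_broto"),
      moran = comp_autocorr(ch, config, "moran"),
      geary = comp_autocorr(ch, config, "geary"),
      ctd = comp_ctd(ch),
      socn = socn_values(ch, config$max_lag),
      qso = comp_qso(ch, config),
      pseaac = comp_pseaac(ch, config)
    )
  })
  unlist(parts, use.names = FALSE)
}

composite_colnames <- function(config) {
  unlist(lapply(config$families, function(fam) {
    switch(fam,
      aac = paste0("caac_", AMINO_ACIDS),
      moreau_broto = ,
      moran = ,
      geary = as.vector(outer(seq_len(config$max_lag),
                              config$properties,
                              function(d, p) paste0(fam, "_", p, "_lag", d))),
      ctd = unlist(lapply(names(CTD_GROUPS), function(p) {
        c(paste0("ctd_comp_", p, "_", 1:3),
          paste0("ctd_trans_", p, "_", c("12", "13", "23")),
          paste0("ctd_dist_", p, "_", rep(1:3, each = 5), "_",
                 rep(c("first", "q25", "q50", "q75", "last"), 3)))
      })),
      socn = paste0("socn_lag", seq_len(config$max_lag)),
      qso = c(paste0("qso_", AMINO_ACIDS), paste0("qso_lag", seq_len(config$max_lag))),
      pseaac = c(paste0("pseaac_", AMINO_ACIDS),
                 paste0("pseaac_theta", seq_len(config$pseaac_lambda)))
    )
  }), use.names = FALSE)
}

#' Composite physicochemical sequence descriptors
#'
#' Concatenates, in registry order, the families selected in `config`:
#' amino-acid composition (frequencies), normalized Moreau-Broto, Moran and
#' Geary autocorrelations over eight standardized physicochemical scales
#' (max lag 30), composition/transition/distribution (CTD) descriptors over
#' the seven standard property groupings, sequence-order-coupling numbers,
#' quasi-sequence-order descriptors (weight 0.1) and type-I pseudo-amino-acid
#' composition (lambda 30, weight 0.05). The total dimension is given by
#' [composite_dimensions()]; it is constant across chains for a fixed config.
#'
#' Chains shorter than `max_lag + 1` residues have their lag-dependent terms
#' computed up to length - 1 and zero-padded, with a warning.
#'
#' @param chains Tibble with columns `id`, `sequence`.
#' @param config A [composite_config()].
#' @return A tibble: `id` plus one column per descriptor element.
#' @export
feat_composite <- function(chains, config = composite_config()) {
  assert_chains_tbl(chains)
  if (!inherits(config, "composite_config")) abort("`config` must be a composite_config().")
  max_needed <- max(config$max_lag, config$pseaac_lambda)
  short <- nchar(chains$sequence) < max_needed + 1L
  if (any(short)) {
    warn(sprintf(
      "Chain(s) %s shorter than %d residues: lag terms truncated to length - 1 and zero-padded.",
      paste(chains$id[short], collapse = ", "), max_needed + 1L
    ))
  }
  m <- t(vapply(chains$sequence, composite_one,
                numeric(sum(composite_dimensions(config))), config = config))
  colnames(m) <- composite_colnames(config)
  rownames(m) <- chains$id
  matrix_to_tbl(m)
}
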
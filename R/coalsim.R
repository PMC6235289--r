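# Coalescent genealogy and sequence simulation.
#
# Rate conventions (used consistently everywhere):
#   * time is measured in units where each pair of lineages coalesces at
#     rate 1, so the expected TMRCA of a random pair is 1;
#   * mutations occur at rate theta/2 per site per unit time at mutational
#     equilibrium, so the expected pairwise diversity per site is theta
#     (up to a small multiple-hit correction);
#   * recombination breakpoints fall on the integer boundaries interior to a
#     lineage's ancestral span, at rate rho/2 per boundary per lineage, so
#     that the expected number of breakpoints separating a random pair is
#     rho per site boundary (total scaled rate rho*(L-1), approximately
#     rho*L).
#
# The Kimura two-parameter process is parameterized so that a mutation event
# is a transition with probability kappa/(kappa + 1) (for gc_bias = 1):
# observed transition:transversion counts then converge to kappa:1. GC bias
# multiplies all rates into {G,C} by beta, giving a reversible chain with
# stationary GC fraction beta/(1 + beta).

#' Simulation configuration for coalescent loci
#'
#' @param n sample size (number of leaves / reads), >= 2
#' @param L number of sites
#' @param theta coalescent-scaled mutation rate per site (expected pairwise
#'   diversity per site)
#' @param rho coalescent-scaled recombination rate per site
#' @param kappa transition/transversion ratio of the K2P mutation process
#' @param ancestral ancestral sequence of length L, or "random" to draw from
#'   the stationary base composition
#' @param gc_bias beta, ratio of (A/T to G/C) over (G/C to A/T) mutation
#'   rates; 1 = unbiased
#' @param seed integer seed, or NULL to use the current RNG state
#' @return object of class `sim_config`
#' @export
sim_config <- function(n, L = 400, theta = 0.02, rho = 0, kappa = 10,
                       ancestral = "random", gc_bias = 1, seed = NULL) {
  stopifnot(n >= 2, theta >= 0, rho >= 0, kappa > 0, gc_bias > 0, L >= 1)
  if (!identical(ancestral, "random")) stopifnot(nchar(ancestral) == L)
  structure(list(n = as.integer(n), L = as.integer(L), theta = theta,
                 rho = rho, kappa = kappa, ancestral = ancestral,
                 gc_bias = gc_bias, seed = seed), class = "sim_config")
}

#' K2P mutation rate structure with optional GC bias
#'
#' @param theta scaled mutation rate per site
#' @param kappa transition/transversion ratio
#' @param beta GC bias factor
#' @return list with rate matrix `W` (rows = current base), total rates `mu`,
#'   dominating rate `mu_max`, and stationary composition `pi`
#' @export
mutation_rates <- function(theta, kappa, beta = 1) {
  W <- matrix(0, 4, 4, dimnames = list(NUCS, NUCS))
  for (a in NUCS) for (b in NUCS) {
    if (a == b) next
    w <- if (unname(TRANSITION_PARTNER[a]) == b) kappa else 0.5
    if (b %in% c("G", "C")) w <- w * beta
    W[a, b] <- w
  }
  pi <- c(A = 1, C = beta, G = beta, T = 1)
  pi <- pi / sum(pi)
  mu <- rowSums(W)
  mean_rate <- sum(pi * mu)
  scale <- if (mean_rate > 0) (theta / 2) / mean_rate else 0
  list(W = W * scale, mu = mu * scale, mu_max = max(mu * scale), pi = pi)
}

# ---- material bookkeeping for the ancestral recombination graph ----------
# A lineage's ancestral material is a per-site group index (0 = site not
# carried) plus one descendant-leaf set per group.

compact_material <- function(m) {
  used <- sort(unique(m$groups[m$groups > 0L]))
  if (length(used) == 0) return(NULL)
  idx <- match(m$groups, used)
  idx[is.na(idx)] <- 0L
  list(groups = idx, leafsets = m$leafsets[used])
}

merge_material <- function(mA, mB) {
  gA <- mA$groups; gB <- mB$groups
  present <- gA > 0L | gB > 0L
  key <- ifelse(present, paste0(gA, "_", gB), NA)
  ukey <- unique(key[present])
  groups <- integer(length(gA))
  leafsets <- vector("list", length(ukey))
  for (i in seq_along(ukey)) {
    sel <- present & key == ukey[i]
    groups[sel] <- i
    ab <- as.integer(strsplit(ukey[i], "_", fixed = TRUE)[[1]])
    la <- if (ab[1] > 0) mA$leafsets[[ab[1]]] else integer(0)
    lb <- if (ab[2] > 0) mB$leafsets[[ab[2]]] else integer(0)
    leafsets[[i]] <- sort(c(la, lb))
  }
  list(groups = groups, leafsets = leafsets)
}

split_material <- function(m, cut) {
  sites <- seq_along(m$groups) - 1L
  left <- m; right <- m
  left$groups[sites >= cut] <- 0L
  right$groups[sites < cut] <- 0L
  list(left = compact_material(left), right = compact_material(right))
}

material_span <- function(m) {
  carried <- which(m$groups > 0L)
  c(lo = carried[1] - 1L, hi = carried[length(carried)])
}

#' Sample a coalescent genealogy (Kingman tree or recombinant ARG)
#'
#' @param config a [sim_config]
#' @param method "auto" uses a plain Kingman sampler when rho = 0 and the
#'   ancestral recombination graph otherwise; "kingman" and "arg" force a
#'   path (the arg path with rho = 0 is used as a cross-check of the two
#'   samplers)
#' @param max_leaves ARG cost guard: with more leaves than this the sample
#'   is subsampled with a warning
#' @return object of class `genealogy`: branches with creation/termination
#'   times and per-site descendant leaf sets, coalescence/recombination
#'   events, per-site TMRCA, and recombination breakpoints
#' @export
sample_genealogy <- function(config, method = c("auto", "kingman", "arg"),
                             max_leaves = 2000) {
  method <- match.arg(method)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (method == "auto") method <- if (config$rho == 0) "kingman" else "arg"
  if (method == "arg" && config$n > max_leaves) {
    warning(sprintf("subsampling ARG from %d to %d leaves", config$n, max_leaves))
    config$n <- as.integer(max_leaves)
  }
  gen <- if (method == "kingman") sample_kingman(config) else sample_arg(config)
  gen$config <- config
  gen$method <- method
  gen
}

sample_kingman <- function(config) {
  n <- config$n; L <- config$L
  if (config$rho > 0)
    stop("kingman sampler requires rho = 0")
  branches <- vector("list", 2 * n - 1)
  for (i in seq_len(n))
    branches[[i]] <- list(t0 = 0, t1 = NA_real_, leaves = i, groups = NULL)
  events <- list()
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  while (length(active) > 1) {
    k <- length(active)
    t <- t + stats::rexp(1, k * (k - 1) / 2)
    pick <- sample(active, 2)
    branches[[pick[1]]]$t1 <- t
    branches[[pick[2]]]$t1 <- t
    branches[[nxt]] <- list(t0 = t, t1 = NA_real_,
                            leaves = sort(c(branches[[pick[1]]]$leaves,
                                            branches[[pick[2]]]$leaves)),
                            groups = NULL)
    events[[length(events) + 1]] <- list(type = "coal", t = t,
                                         c1 = pick[1], c2 = pick[2],
                                         parent = nxt)
    active <- c(setdiff(active, pick), nxt)
    nxt <- nxt + 1L
  }
  structure(list(n = n, L = L, branches = branches, events = events,
                 tmrca = rep(t, L), breakpoints = integer(0)),
            class = "genealogy")
}

sample_arg <- function(config) {
  n <- config$n; L <- config$L; rho <- config$rho
  branches <- list()
  for (i in seq_len(n))
    branches[[i]] <- list(t0 = 0, t1 = NA_real_, leaves = NULL,
                          groups = rep(1L, L), leafsets = list(i))
  events <- list()
  active <- seq_len(n)
  site_count <- rep(n, L)
  tmrca <- rep(NA_real_, L)
  breakpoints <- integer(0)
  t <- 0
  while (length(active) > 1) {
    k <- length(active)
    spans <- vapply(active, function(id) {
      sp <- material_span(branches[[id]])
      max(unname(sp["hi"] - sp["lo"]) - 1L, 0L)
    }, 0L)
    coal_rate <- k * (k - 1) / 2
    rec_rate <- (rho / 2) * sum(spans)
    t <- t + stats::rexp(1, coal_rate + rec_rate)
    if (stats::runif(1) < rec_rate / (coal_rate + rec_rate)) {
      # recombination: split one lineage at an interior boundary
      id <- active[sample.int(k, 1, prob = spans)]
      sp <- material_span(branches[[id]])
      cut <- unname(sp["lo"]) + sample.int(unname(sp["hi"] - sp["lo"]) - 1L, 1)
      halves <- split_material(branches[[id]], cut)
      branches[[id]]$t1 <- t
      pl <- length(branches) + 1L
      branches[[pl]] <- c(list(t0 = t, t1 = NA_real_, leaves = NULL),
                          halves$left)
      pr <- length(branches) + 1L
      branches[[pr]] <- c(list(t0 = t, t1 = NA_real_, leaves = NULL),
                          halves$right)
      events[[length(events) + 1]] <- list(type = "rec", t = t, child = id,
                                           pl = pl, pr = pr, cut = cut)
      breakpoints <- union(breakpoints, as.integer(cut))
      active <- c(setdiff(active, id), pl, pr)
    } else {
      pick <- sample(active, 2)
      m1 <- branches[[pick[1]]]; m2 <- branches[[pick[2]]]
      merged <- merge_material(m1, m2)
      overlap <- m1$groups > 0L & m2$groups > 0L
      site_count[overlap] <- site_count[overlap] - 1L
      done <- overlap & site_count == 1L
      if (any(done)) {
        tmrca[done] <- t
        site_count[done] <- 0L
        merged$groups[done] <- 0L
        merged <- compact_material(merged)
      }
      branches[[pick[1]]]$t1 <- t
      branches[[pick[2]]]$t1 <- t
      active <- setdiff(active, pick)
      parent <- NA_integer_
      if (!is.null(merged)) {
        parent <- length(branches) + 1L
        branches[[parent]] <- c(list(t0 = t, t1 = NA_real_, leaves = NULL),
                                merged)
        active <- c(active, parent)
      }
      events[[length(events) + 1]] <- list(type = "coal", t = t,
                                           c1 = pick[1], c2 = pick[2],
                                           parent = parent)
    }
  }
  structure(list(n = n, L = L, branches = branches, events = events,
                 tmrca = tmrca, breakpoints = sort(breakpoints)),
            class = "genealogy")
}

#' Total branch length of a genealogy (coalescent units)
#'
#' For a non-recombining genealogy this is the classical total tree length
#' with expectation 2 * sum_{k=1}^{n-1} 1/k.
#' @param genealogy a `genealogy`
#' @return total length over all branches (ARG branches weighted by 1
#'   regardless of how many sites they carry)
#' @export
total_branch_length <- function(genealogy) {
  sum(vapply(genealogy$branches, function(b)
    if (is.na(b$t1)) 0 else b$t1 - b$t0, 0))
}

#' Per-site TMRCA of a pair of leaves
#'
#' @param genealogy a `genealogy`
#' @param i,j leaf indices
#' @return numeric vector of length L: the coalescence time of leaves i and
#'   j at each site
#' @export
pair_tmrca <- function(genealogy, i, j) {
  L <- genealogy$L
  out <- rep(Inf, L)
  for (ev in genealogy$events) {
    if (ev$type != "coal") next
    b1 <- genealogy$branches[[ev$c1]]
    b2 <- genealogy$branches[[ev$c2]]
    if (is.null(b1$groups)) {     # Kingman: full material
      joins <- (i %in% b1$leaves && j %in% b2$leaves) ||
        (j %in% b1$leaves && i %in% b2$leaves)
      if (joins) out[] <- pmin(out, ev$t)
    } else {
      in1 <- function(x) vapply(b1$leafsets, function(ls) x %in% ls, TRUE)
      in2 <- function(x) vapply(b2$leafsets, function(ls) x %in% ls, TRUE)
      i1 <- in1(i); j1 <- in1(j); i2 <- in2(i); j2 <- in2(j)
      both <- b1$groups > 0L & b2$groups > 0L
      sel <- both & ((i1[pmax(b1$groups, 1L)] & j2[pmax(b2$groups, 1L)]) |
                       (j1[pmax(b1$groups, 1L)] & i2[pmax(b2$groups, 1L)]))
      out[sel] <- pmin(out[sel], ev$t)
    }
  }
  out
}

#' Newick string of the marginal tree at one site
#'
#' @param genealogy a `genealogy`
#' @param site 1-based site index
#' @return newick string with branch lengths in coalescent units
#' @export
marginal_tree_newick <- function(genealogy, site = 1) {
  carries <- function(id) {
    b <- genealogy$branches[[id]]
    if (is.null(b$groups)) TRUE else b$groups[site] > 0L
  }
  node <- list()   # branch id -> list(str, t)
  for (i in seq_len(genealogy$n))
    node[[as.character(i)]] <- list(str = paste0("L", i), t = 0)
  for (ev in genealogy$events) {
    if (ev$type == "rec") {
      key <- as.character(ev$child)
      if (!is.null(node[[key]])) {
        keep <- if (carries(ev$pl)) ev$pl else if (carries(ev$pr)) ev$pr else NA
        if (!is.na(keep)) node[[as.character(keep)]] <- node[[key]]
        node[[key]] <- NULL
      }
    } else {
      k1 <- as.character(ev$c1); k2 <- as.character(ev$c2)
      h1 <- !is.null(node[[k1]]); h2 <- !is.null(node[[k2]])
      if (h1 && h2) {
        s <- sprintf("(%s:%.8f,%s:%.8f)",
                     node[[k1]]$str, ev$t - node[[k1]]$t,
                     node[[k2]]$str, ev$t - node[[k2]]$t)
        node[[k1]] <- NULL; node[[k2]] <- NULL
        if (!is.na(ev$parent) && carries(ev$parent)) {
          node[[as.character(ev$parent)]] <- list(str = s, t = ev$t)
        } else {
          # site MRCA reached at this event
          return(paste0(s, ";"))
        }
      } else if (h1 || h2) {
        key <- if (h1) k1 else k2
        if (!is.na(ev$parent) && carries(ev$parent)) {
          node[[as.character(ev$parent)]] <- node[[key]]
        }
        if (!(!is.na(ev$parent) && carries(ev$parent))) {
          # sole carrier merged into a parent that no longer tracks the site
          return(paste0(node[[key]]$str, ";"))
        }
        node[[key]] <- NULL
      }
    }
  }
  if (length(node) == 1) return(paste0(node[[1]]$str, ";"))
  stop("marginal tree extraction failed")
}

#' Overlay K2P mutations on a sampled genealogy
#'
#' Mutations are a Poisson process at rate theta/2 per carried site per unit
#' branch time (uniformization against the fastest per-base rate, so the
#' state-dependent GC-biased process is exact). Applied oldest-first so each
#' event sees the current base of the whole descendant leaf set.
#'
#' @param genealogy a `genealogy` from [sample_genealogy]
#' @param config the [sim_config] (theta, kappa, gc_bias, ancestral)
#' @return the genealogy with `$sequences` (character vector of n strings)
#'   and `$ancestral` added
#' @export
overlay_mutations <- function(genealogy, config) {
  n <- genealogy$n; L <- genealogy$L
  rates <- mutation_rates(config$theta, config$kappa, config$gc_bias)
  anc <- if (identical(config$ancestral, "random"))
    sample(NUCS, L, replace = TRUE, prob = rates$pi) else
    strsplit(config$ancestral, "")[[1]]
  seqs <- matrix(rep(anc, each = n), nrow = n)
  if (rates$mu_max > 0) {
    mut_site <- integer(0); mut_time <- numeric(0); mut_branch <- integer(0)
    for (bi in seq_along(genealogy$branches)) {
      b <- genealogy$branches[[bi]]
      if (is.na(b$t1)) next
      nsites <- if (is.null(b$groups)) L else sum(b$groups > 0L)
      nm <- stats::rpois(1, rates$mu_max * nsites * (b$t1 - b$t0))
      if (nm == 0) next
      sites <- if (is.null(b$groups)) sample.int(L, nm, replace = TRUE) else
        which(b$groups > 0L)[sample.int(nsites, nm, replace = TRUE)]
      mut_site <- c(mut_site, sites)
      mut_time <- c(mut_time, stats::runif(nm, b$t0, b$t1))
      mut_branch <- c(mut_branch, rep(bi, nm))
    }
    ord <- order(mut_time, decreasing = TRUE)
    for (m in ord) {
      b <- genealogy$branches[[mut_branch[m]]]
      s <- mut_site[m]
      leaves <- if (is.null(b$groups)) b$leaves else b$leafsets[[b$groups[s]]]
      cur <- seqs[leaves[1], s]
      if (stats::runif(1) > rates$mu[cur] / rates$mu_max) next
      target <- sample(NUCS, 1, prob = rates$W[cur, ])
      seqs[leaves, s] <- target
    }
  }
  genealogy$sequences <- apply(seqs, 1, paste, collapse = "")
  genealogy$ancestral <- paste(anc, collapse = "")
  genealogy
}

#' Gamma-sampling null for asexual allele frequencies
#'
#' Draws K gamma(shape = thetaL/K, scale = 1) variables, normalizes, and
#' sorts descending: in the K -> infinity limit this is the Poisson-Dirichlet
#' frequency spectrum of the neutral asexual infinite-alleles model with
#' scaled locus mutation rate thetaL.
#'
#' @param thetaL scaled mutation rate for the whole locus (theta * L)
#' @param K number of gamma variables (resolution of the approximation)
#' @param seed optional integer seed
#' @return numeric vector of K non-negative frequencies summing to 1, sorted
#'   descending
#' @export
sample_asexual_frequencies <- function(thetaL, K = 5000, seed = NULL) {
  stopifnot(thetaL > 0, K >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- stats::rgamma(K, shape = thetaL / K, scale = 1)
  if (sum(g) == 0) g[sample.int(K, 1)] <- 1   # guard against underflow
  sort(g / sum(g), decreasing = TRUE)
}

#' Simulate one locus allele table under the coalescent
#'
#' Samples a genealogy with `depth` leaves, overlays mutations, and collapses
#' identical leaf sequences into alleles with read counts. The ancestral
#' sequence fills the reference slot.
#'
#' @param config a [sim_config] with n equal to `depth`
#' @param depth number of reads (leaves)
#' @param locus_id identifier for the resulting table
#' @param method genealogy sampler passed to [sample_genealogy]
#' @return a [locus_table]
#' @export
simulate_locus <- function(config, depth = config$n, locus_id = "sim",
                           method = "auto") {
  stopifnot(depth == config$n)
  gen <- sample_genealogy(config, method = method)
  gen <- overlay_mutations(gen, config)
  collapse_reads_to_table(gen$sequences, locus_id, ref_b = gen$ancestral)
}

#' Collapse a set of reads into a locus allele table
#' @param reads character vector of equal-length sequences
#' @param locus_id identifier
#' @param ref_b,ref_a optional references
#' @param coding_intervals optional annotation
#' @return a [locus_table]
#' @export
collapse_reads_to_table <- function(reads, locus_id, ref_b = NULL,
                                    ref_a = NULL, coding_intervals = NULL) {
  tab <- table(reads)
  locus_table(locus_id, names(tab), as.integer(tab), ref_b = ref_b,
              ref_a = ref_a, coding_intervals = coding_intervals)
}
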
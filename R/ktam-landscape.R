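## Minimal-barrier landscape search.
##
## All attachment pathways are monotone in assembly size, so the minimax
## free energy to reach a state is found by a best-first (Dijkstra-style)
## search in which the priority of a state is the lowest achievable maximum
## G along any pathway reaching it.  States are deduplicated by canonical
## key (translation, and tube rotation, invariant).

# simple binary min-heap over (priority, id)
heapNew <- function() {
  env <- new.env(parent = emptyenv())
  env$f <- numeric(0); env$id <- integer(0)
  env
}
heapPush <- function(h, f, id) {
  n <- length(h$f) + 1L
  h$f[n] <- f; h$id[n] <- id
  while (n > 1L) {
    p <- n %/% 2L
    if (h$f[p] <= h$f[n]) break
    tmp <- h$f[p]; h$f[p] <- h$f[n]; h$f[n] <- tmp
    tmp <- h$id[p]; h$id[p] <- h$id[n]; h$id[n] <- tmp
    n <- p
  }
}
heapPop <- function(h) {
  if (!length(h$f)) return(NULL)
  top <- c(h$f[1], h$id[1])
  n <- length(h$f)
  h$f[1] <- h$f[n]; h$id[1] <- h$id[n]
  h$f <- h$f[-n]; h$id <- h$id[-n]
  n <- n - 1L; i <- 1L
  while (TRUE) {
    l <- 2L * i; r <- l + 1L; s <- i
    if (l <= n && h$f[l] < h$f[s]) s <- l
    if (r <= n && h$f[r] < h$f[s]) s <- r
    if (s == i) break
    tmp <- h$f[s]; h$f[s] <- h$f[i]; h$f[i] <- tmp
    tmp <- h$id[s]; h$id[s] <- h$id[i]; h$id[i] <- tmp
    i <- s
  }
  top
}

#' Minimal minimax barrier to a given assembly size (best-first search)
#'
#' Exact search over canonicalized connected assembly states: among all
#' attachment orderings reaching any connected assembly of \code{size}
#' monomers, finds the ordering minimizing the maximum free energy along the
#' way.  Priority-queue best-first with priority = max-G-so-far;
#' lexicographic tie-breaking on canonical labels is implicit in insertion
#' order.
#'
#' @param arch an [Architecture-class].
#' @param params a [KtamParams-class].
#' @param size target assembly size (monomers).
#' @return list with \code{barrier} (minimax G, decades), \code{Gprofile}
#'   (G after each attachment along the optimal pathway, starting at 0),
#'   \code{bonds} (bonds formed at each attachment) and \code{pathway}
#'   (placement labels).
#' @export
minimaxBarrier <- function(arch, params, size) {
  size <- as.integer(size)
  if (size < 1L) stop("size must be at least 1")
  states <- new.env(parent = emptyenv(), hash = TRUE)  # key -> record id
  recState <- list(); recF <- numeric(); recN <- integer()
  recB <- numeric(); recG <- numeric(); recParent <- integer()
  recLabel <- character()
  h <- heapNew()
  addState <- function(state, f, N, B, G, parent, label) {
    id <- length(recState) + 1L
    recState[[id]] <<- state
    recF[id] <<- f; recN[id] <<- N; recB[id] <<- B; recG[id] <<- G
    recParent[id] <<- parent; recLabel[id] <<- label
    heapPush(h, f, id)
    id
  }
  empty <- newAssembly(arch)
  assign(canonicalKey(arch, empty), 1L, envir = states)
  addState(empty, 0, 0L, 0, 0, 0L, "")
  done <- new.env(parent = emptyenv(), hash = TRUE)
  repeat {
    top <- heapPop(h)
    if (is.null(top)) stop("search exhausted before reaching target size")
    id <- as.integer(top[2]); f <- top[1]
    key <- canonicalKey(arch, recState[[id]])
    if (!is.null(done[[key]])) next
    done[[key]] <- TRUE
    if (recN[id] == size) {
      path <- integer()
      cur <- id
      while (cur != 0L) { path <- c(cur, path); cur <- recParent[cur] }
      return(list(barrier = f,
                  Gprofile = recG[path],
                  bonds = diff(c(0, recB[path]))[-1][seq_len(length(path) - 1L)],
                  pathway = recLabel[path][-1]))
    }
    state <- recState[[id]]
    for (pl in candidatePlacements(arch, state)) {
      b <- attachmentBonds(arch, state, pl)
      if (recN[id] > 0L && b == 0L) next  # stay connected via bonds
      ns <- placeMonomer(arch, state, pl)
      nkey <- canonicalKey(arch, ns)
      if (!is.null(done[[nkey]])) next
      G <- freeEnergy(params, recN[id] + 1L, recB[id] + b)
      nf <- max(f, G)
      prev <- states[[nkey]]
      if (!is.null(prev) && recF[prev] <= nf) next
      lbl <- if (arch@kind == "CS") paste0(pl$axis, pl$pos)
             else paste0("(", pl[1], ",", pl[2], ")")
      nid <- addState(ns, nf, recN[id] + 1L, recB[id] + b, G, id, lbl)
      assign(nkey, nid, envir = states)
    }
  }
}

#' Exhaustive layered enumeration of minimal barriers (oracle)
#'
#' Independent check of [minimaxBarrier()]: enumerates every connected
#' assembly state of each size (no priority queue, no early exit) and
#' propagates the minimal achievable maximum G layer by layer over all
#' connected attachment orders.
#'
#' @inheritParams minimaxBarrier
#' @param max_size largest assembly size to enumerate.
#' @return numeric vector: minimal minimax barrier for sizes 1..max_size.
#' @export
enumerateBarriers <- function(arch, params, max_size) {
  layer <- list(list(state = newAssembly(arch), f = 0, B = 0))
  names(layer) <- canonicalKey(arch, newAssembly(arch))
  out <- numeric(max_size)
  for (s in seq_len(max_size)) {
    nxt <- new.env(parent = emptyenv(), hash = TRUE)
    for (rec in layer) {
      for (pl in candidatePlacements(arch, rec$state)) {
        b <- attachmentBonds(arch, rec$state, pl)
        if (assemblySize(rec$state) > 0L && b == 0L) next
        ns <- placeMonomer(arch, rec$state, pl)
        key <- canonicalKey(arch, ns)
        G <- freeEnergy(params, s, rec$B + b)
        f <- max(rec$f, G)
        old <- nxt[[key]]
        if (is.null(old) || old$f > f)
          nxt[[key]] <- list(state = ns, f = f, B = rec$B + b)
      }
    }
    layer <- as.list(nxt)
    out[s] <- min(vapply(layer, function(r) r$f, numeric(1)))
  }
  out
}

csStaircaseProfile <- function(n, params, max_size) {
  # Minimal-barrier CS pathway: alternate y/x additions keeping the
  # assembly a maximally-crossing block (B = floor(N^2/4) for N <= 2n),
  # then steady-state ribbon growth at n bonds per slat.
  N <- seq_len(max_size)
  B <- ifelse(N <= 2 * n, floor(N^2 / 4), n^2 + (N - 2 * n) * n)
  G <- freeEnergy(params, N, B)
  list(G = G, B = B,
       labels = ifelse(N %% 2 == 1, paste0("y", (N - 1) %/% 2),
                       paste0("x", N %/% 2 - 1)))
}

#' Minimal-barrier nucleation landscape and critical nucleus
#'
#' Computes the minimal-barrier free-energy landscape for spontaneous
#' nucleation: the attachment ordering (over connected assemblies)
#' minimizing the maximum of \code{G = N * gMC - B * gSE}, its barrier, and
#' the critical nucleus at the barrier.
#'
#' For crisscross slats the minimal pathway is the alternating "staircase"
#' (each new slat crosses every perpendicular slat of the block), which is
#' provably optimal for this free-energy form because \code{B <= floor(N^2/4)}
#' for any bipartite crossing state; \code{method = "staircase"} evaluates it
#' in closed form.  \code{method = "exact"} runs the best-first search of
#' [minimaxBarrier()] (feasible for small \code{max_size}); \code{"auto"}
#' picks the staircase for CS and the exact search for tiles.
#'
#' @inheritParams minimaxBarrier
#' @param max_size largest assembly size searched.  If the profile is still
#'   rising at \code{max_size} the barrier is unbracketed and an error is
#'   thrown.
#' @param method search method, see Details.
#' @return a [NucleationLandscape-class].
#' @examples
#' arch <- architecture("CS", n = 6)
#' p <- ktamParams(arch, epsilon = 2, concentration = 1e-6)
#' criticalNucleus(arch, p, max_size = 16)
#' @export
criticalNucleus <- function(arch, params, max_size = 4L * arch@n,
                            method = c("auto", "staircase", "exact")) {
  method <- match.arg(method)
  if (method == "auto") method <- if (arch@kind == "CS") "staircase" else "exact"
  if (method == "staircase" && arch@kind != "CS")
    stop("the staircase pathway is defined for CS architectures only")
  if (method == "staircase") {
    sp <- csStaircaseProfile(arch@n, params, max_size)
    Gfull <- c(0, sp$G); bonds <- diff(c(0, sp$B)); labels <- sp$labels
  } else {
    res <- minimaxBarrier(arch, params, max_size)
    Gfull <- res$Gprofile; bonds <- res$bonds; labels <- res$pathway
  }
  bar <- max(Gfull)
  if (which.max(Gfull) == length(Gfull) &&
      Gfull[length(Gfull)] > Gfull[length(Gfull) - 1L] + 1e-9)
    stop("unbracketed: the free-energy profile is still rising at max_size; ",
         "increase max_size")
  tol <- 1e-6 * max(1, abs(bar))
  atMax <- which(Gfull >= bar - tol) - 1L      # in monomer counts
  cap <- if (arch@kind == "CS") 2L * arch@n else max_size
  csize <- max(atMax[atMax <= cap], atMax[1])
  Bcum <- cumsum(c(0, bonds))
  pathway <- data.frame(N = seq_along(labels), placement = labels,
                        bonds = bonds, dG = diff(Gfull),
                        G = Gfull[-1], stringsAsFactors = FALSE)
  new("NucleationLandscape", pathway = pathway, Gprofile = Gfull,
      barrier = bar, criticalSize = as.integer(csize),
      bondsAtCritical = Bcum[csize + 1L], method = method, arch = arch,
      params = params)
}

#' Calibrated analytic nucleation barriers
#'
#' Continuum (real-valued cluster size) saddle-point barrier for an
#' architecture, the form under which the four benchmark barriers of the
#' tile-versus-slat comparison are reproduced (10.8 ST, 13.9 HT, 34.4 CS
#' n=6, 45.8 CS n=8 decades at 1 uM and epsilon = 2):
#' \itemize{
#'   \item CS: staircase saddle \code{n * gMC^2 / (gMC + eps)} at
#'     \code{2 n gMC / (gMC + eps)} monomers;
#'   \item ST: rectangle saddle \code{gSE^2 / eps} on the square lattice,
#'     capped by the tube-wrap pathway \code{(m + 1)(gMC - gSE)} once the
#'     saddle outgrows the circumference m;
#'   \item HT: hexagonal (Wulff-shape) saddle on the triangular lattice,
#'     capped by the ring pathway \code{m (gMC - gSE) + max(0, gMC - 2 gSE)}.
#' }
#' Sub-reversible parameters (effective epsilon < 0) give an infinite
#' barrier.
#'
#' @inheritParams minimaxBarrier
#' @return list with \code{barrier} (decades) and \code{criticalSize}
#'   (monomers, real-valued).
#' @export
analyticBarrier <- function(arch, params) {
  g <- params@gMC; gse <- params@gSE
  if (arch@kind == "CS") {
    eps <- arch@n * gse - g
    if (eps < 0) return(list(barrier = Inf, criticalSize = Inf))
    xstar <- arch@n * g / (g + eps)
    return(list(barrier = g * xstar, criticalSize = 2 * xstar))
  }
  m <- arch@circumference
  if (arch@kind == "ST") {
    eps <- 2 * gse - g
    capped <- (m + 1) * (g - gse)
    if (eps < 0) return(list(barrier = Inf, criticalSize = Inf))
    if (eps == 0 || gse / eps >= m)
      return(list(barrier = capped, criticalSize = m + 1))
    astar <- gse / eps
    list(barrier = gse^2 / eps, criticalSize = astar^2)
  } else {
    eps <- 3 * gse - g
    capped <- m * (g - gse) + max(0, g - 2 * gse)
    if (eps < 0) return(list(barrier = Inf, criticalSize = Inf))
    if (eps == 0) return(list(barrier = capped, criticalSize = m + 1))
    sstar <- gse / eps + 0.5
    flat <- -eps * (3 * sstar^2 - 3 * sstar + 1) + (6 * sstar - 3) * gse
    if (2 * sstar - 1 >= m || capped < flat)
      list(barrier = capped, criticalSize = m + 1)
    else
      list(barrier = flat, criticalSize = 3 * sstar^2 - 3 * sstar + 1)
  }
}

#' Barrier at the reversible limit
#'
#' Free energy of nucleation at epsilon -> 0 (per-bond energy gMC / n):
#' \code{n * gMC} for CS, \code{(m + 1) gMC / 2} for an ST tube of
#' circumference m, \code{(2 m + 1) gMC / 3} for an HT tube.
#'
#' @inheritParams minimaxBarrier
#' @param g_mc monomer cost in decades.
#' @return barrier in decades.
#' @export
reversibleBarrier <- function(arch, g_mc) {
  switch(arch@kind,
         CS = arch@n * g_mc,
         ST = (arch@circumference + 1) * g_mc / 2,
         HT = (2 * arch@circumference + 1) * g_mc / 3)
}

#' Barrier versus irreversibility curve
#'
#' Sweeps epsilon at fixed gMC (the per-bond energy follows as
#' \code{gSE = (gMC + eps)/n}) and reports the nucleation barrier and
#' critical size.  Both are non-increasing in epsilon; where the critical
#' nucleus composition is constant the slope is exactly \code{-B*/n}.
#'
#' @inheritParams minimaxBarrier
#' @param eps_grid non-negative, increasing epsilon values (decades).
#' @param method \code{"analytic"} (calibrated continuum saddle) or
#'   \code{"staircase"} (discrete CS landscape).
#' @return data.frame (epsilon, barrier, critical_size).
#' @export
barrierVsEpsilon <- function(arch, params, eps_grid,
                             method = c("analytic", "staircase")) {
  method <- match.arg(method)
  if (is.unsorted(eps_grid, strictly = FALSE) || any(eps_grid < 0))
    stop("eps_grid must be non-negative and increasing")
  if (method == "staircase" && arch@kind != "CS")
    stop("staircase curves are defined for CS architectures only")
  rows <- lapply(eps_grid, function(eps) {
    p <- ktamParams(arch@n, epsilon = eps, gMC = params@gMC)
    if (method == "analytic") {
      ab <- analyticBarrier(arch, p)
      c(eps, ab$barrier, ab$criticalSize)
    } else {
      ls <- criticalNucleus(arch, p, max_size = 2L * arch@n + 4L,
                            method = "staircase")
      c(eps, ls@barrier, ls@criticalSize)
    }
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("epsilon", "barrier", "critical_size")
  out
}

#' Match architectures at the reversible limit
#'
#' Finds parameters for \code{target_arch} whose free energy of nucleation
#' at epsilon -> 0 equals that of the reference system, the construction
#' under which tile and slat systems are compared on equal footing.  For
#' tiles the integer tube circumference closest to an exact match is chosen
#' and the monomer cost rescaled (equivalently, the concentration shifted
#' slightly) so the match is exact; the adjustment is bounded to half a
#' decade, beyond which no feasible match exists within the search bounds.
#'
#' @param ref_arch,ref_params the reference system.
#' @param target_arch architecture to be matched (circumference slot is
#'   ignored and solved for).
#' @param max_circumference largest tube circumference searched.
#' @return list with \code{arch} (target with solved circumference),
#'   \code{params} ([KtamParams-class] at epsilon = 0) and
#'   \code{barrier} (the matched reversible barrier, decades).
#' @export
matchArchitectures <- function(ref_arch, ref_params, target_arch,
                               max_circumference = 64L) {
  B0 <- reversibleBarrier(ref_arch, ref_params@gMC)
  if (target_arch@kind == "CS") {
    g <- B0 / target_arch@n
    if (abs(g - ref_params@gMC) > 0.5 + 1e-12)
      stop("no feasible match within search bounds")
    params <- ktamParams(target_arch@n, epsilon = 0, gMC = g)
    return(list(arch = target_arch, params = params, barrier = B0))
  }
  gFor <- function(m) {
    if (target_arch@kind == "ST") 2 * B0 / (m + 1) else 3 * B0 / (2 * m + 1)
  }
  ms <- seq_len(max_circumference)
  dev <- abs(vapply(ms, gFor, numeric(1)) - ref_params@gMC)
  m <- ms[which.min(dev)]
  g <- gFor(m)
  if (abs(g - ref_params@gMC) > 0.5 + 1e-12)
    stop("no feasible match within search bounds ",
         "(max_circumference too small)")
  arch <- architecture(target_arch@kind, circumference = m)
  params <- ktamParams(arch@n, epsilon = 0, gMC = g)
  list(arch = arch, params = params, barrier = B0)
}

#' Seeded free-energy landscape
#'
#' Energy profile of seeded CS growth: the seed is modeled purely
#' energetically as a pre-formed edge presenting 2n handle sites, so each of
#' the 2n nucleator captures and every subsequent slat addition makes n
#' bonds, giving \code{dG = gMC - n gSE = -epsilon} per step.  For
#' epsilon > 0 the profile is monotone non-increasing: the seed pre-pays the
#' nucleation barrier.
#'
#' @inheritParams minimaxBarrier
#' @param n_steps number of slat additions profiled.
#' @param capture_bonds bond-equivalent strength of a nucleator capture by
#'   the seed (default n).
#' @return a [NucleationLandscape-class] with \code{method = "seeded"}.
#' @export
landscapeWithSeed <- function(arch, params, n_steps = 6L * arch@n,
                              capture_bonds = arch@n) {
  if (arch@kind != "CS")
    stop("seeded landscapes are defined for CS architectures only")
  n <- arch@n
  bonds <- c(rep(capture_bonds, 2L * n), rep(n, max(0L, n_steps - 2L * n)))
  dG <- params@gMC - bonds * params@gSE
  G <- c(0, cumsum(dG))
  labels <- c(paste0("nucY", seq_len(min(2L * n, n_steps)) - 1L),
              if (n_steps > 2L * n)
                paste0("slat", seq_len(n_steps - 2L * n) - 1L))
  bar <- max(G)
  pathway <- data.frame(N = seq_len(n_steps), placement = labels,
                        bonds = bonds, dG = dG, G = G[-1],
                        stringsAsFactors = FALSE)
  new("NucleationLandscape", pathway = pathway, Gprofile = G, barrier = bar,
      criticalSize = as.integer(which.max(G) - 1L),
      bondsAtCritical = sum(bonds[seq_len(which.max(G) - 1L)]),
      method = "seeded", arch = arch, params = params)
}
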
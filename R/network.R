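## Network topology: populations on 2-D grids, distance-limited gap
## junctions, global probabilistic chemical connectivity, and per-cell leak
## heterogeneity.

.default_sizes <- c(HTC = 49, RTC = 144, IN = 64, RE = 100)

# Square grid coordinates for n = k^2 cells, row-major, in lattice units.
.grid_coords <- function(n) {
  k <- round(sqrt(n))
  if (k * k != n) stop("population size must be a perfect square, got ", n)
  expand.grid(x = seq_len(k) - 1, y = seq_len(k) - 1)[, c("x", "y")]
}

#' Default connectivity rules
#'
#' Chemical pathways are global Bernoulli draws over ordered pairs
#' (probabilities 0.3 for HTC->IN and IN->RTC, 0.2 for the TC-RE loop and
#' RE->RE, 0.05 for RE->IN).  Gap junctions are local: endpoints at most two
#' lattice units apart, connection probability 0.3, with only 20% of RTC
#' cells eligible for HTC-RTC coupling and 20% of RE cells eligible for
#' RE-RE coupling.  Junction resistances: 100 MOhm for HTC-HTC, 300 MOhm
#' for HTC-RTC and RE-RE.
#' @return list with `chem` (data frame) and `gap` (data frame) components.
#' @export
connectivity_rules <- function() {
  list(
    chem = .pathway_table(),
    gap = data.frame(
      pathway = c("HTC-HTC", "HTC-RTC", "RE-RE"),
      a = c("HTC", "HTC", "RE"), b = c("HTC", "RTC", "RE"),
      p = c(0.3, 0.3, 0.3), radius = c(2, 2, 2),
      fraction_b = c(1, 0.2, 0.2), R_g = c(100, 300, 300),
      stringsAsFactors = FALSE)
  )
}

#' Build the thalamic network graph
#'
#' Places the four populations on square grids, draws chemical edges as
#' independent Bernoulli trials per ordered pair, draws local gap junctions
#' (distance at most two lattice units; cross-population distances measured
#' after embedding both grids in the unit square with the HTC lattice
#' spacing as the unit), and assigns heterogeneous leak conductances
#' uniformly within +/-25% of 0.01 mS/cm2.  The graph is a pure function of
#' `(rules, sizes, seed)`.
#'
#' @param seed integer seed controlling all topology randomness.
#' @param sizes named vector of population sizes (perfect squares); defaults
#'   to the full 49/144/64/100-cell circuit.
#' @param rules a [connectivity_rules()] list.
#' @param heterogeneity if `FALSE`, all leak conductances equal 0.01.
#' @return an object of class `thalamic_network`.
#' @export
build_network <- function(seed = 1, sizes = .default_sizes,
                          rules = connectivity_rules(),
                          heterogeneity = TRUE) {
  stopifnot(all(names(.default_sizes) %in% names(sizes)))
  sizes <- sizes[names(.default_sizes)]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  coords <- lapply(sizes, .grid_coords)

  ## chemical edges: independent Bernoulli per ordered pair, no self-pairs
  chem <- list()
  for (i in seq_len(nrow(rules$chem))) {
    r <- rules$chem[i, ]
    n_pre <- sizes[[r$pre]]; n_post <- sizes[[r$post]]
    pre <- rep(seq_len(n_pre), each = n_post)
    post <- rep(seq_len(n_post), times = n_pre)
    if (r$pre == r$post) {
      keep <- pre != post
      pre <- pre[keep]; post <- post[keep]
    }
    draw <- runif(length(pre)) < r$p
    k <- sum(draw)
    chem[[r$pathway]] <- data.frame(
      pathway = rep(r$pathway, k), pre_pop = rep(r$pre, k),
      post_pop = rep(r$post, k), pre = pre[draw], post = post[draw],
      g_ampa = rep(r$g_ampa, k), g_nmda = rep(r$g_nmda, k),
      g_gaba = rep(r$g_gaba, k), E_gaba = rep(r$E_gaba, k),
      std = rep(TRUE, k), stringsAsFactors = FALSE)
  }
  chem <- do.call(rbind, chem)
  rownames(chem) <- NULL

  ## gap junctions: local, per unordered pair, restricted eligibility
  gap <- list()
  for (i in seq_len(nrow(rules$gap))) {
    r <- rules$gap[i, ]
    ca <- coords[[r$a]]; cb <- coords[[r$b]]
    na <- sizes[[r$a]]; nb <- sizes[[r$b]]
    elig_b <- if (r$fraction_b < 1)
      sort(sample(seq_len(nb), round(r$fraction_b * nb))) else seq_len(nb)
    same <- r$a == r$b
    if (same) {
      # unordered pairs with at least one eligible endpoint, distance in the
      # population's own lattice units
      grid <- expand.grid(u = seq_len(na), v = elig_b)
      grid <- grid[grid$u != grid$v, ]
      lo <- pmin(grid$u, grid$v); hi <- pmax(grid$u, grid$v)
      keep <- !duplicated(cbind(lo, hi))
      u <- lo[keep]; v <- hi[keep]
      xa <- ca$x; ya <- ca$y
      d <- sqrt((xa[u] - xa[v])^2 + (ya[u] - ya[v])^2)
    } else {
      # embed both grids in the unit square; one unit = HTC lattice spacing
      ka <- round(sqrt(na)); kb <- round(sqrt(nb))
      ax <- ca$x / (ka - 1); ay <- ca$y / (ka - 1)
      bx <- cb$x / (kb - 1); by <- cb$y / (kb - 1)
      grid <- expand.grid(u = seq_len(na), v = elig_b)
      u <- grid$u; v <- grid$v
      d <- sqrt((ax[u] - bx[v])^2 + (ay[u] - by[v])^2) * (ka - 1)
    }
    ok <- d <= r$radius
    u <- u[ok]; v <- v[ok]
    draw <- runif(length(u)) < r$p
    k <- sum(draw)
    gap[[r$pathway]] <- data.frame(
      pathway = rep(r$pathway, k), pop_a = rep(r$a, k), pop_b = rep(r$b, k),
      a = u[draw], b = v[draw], R_g = rep(r$R_g, k),
      stringsAsFactors = FALSE)
  }
  gap <- do.call(rbind, gap)
  rownames(gap) <- NULL

  g_L <- lapply(sizes, function(n)
    if (heterogeneity) runif(n, 0.0075, 0.0125) else rep(0.01, n))

  structure(list(sizes = sizes, coords = coords, chem = chem, gap = gap,
                 g_L = g_L, seed = seed, rules = rules),
            class = "thalamic_network")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.thalamic_network <- function(x, ...) {
  cat("Thalamic network graph\n")
  cat("  populations:",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "), "\n")
  cat("  chemical edges:", nrow(x$chem), "  gap junctions:", nrow(x$gap), "\n")
  cat("  topology seed:", x$seed, "\n")
  invisible(x)
}

#' Remove connection classes from a network
#'
#' @param network a [build_network()] result.
#' @param what character vector of pathway names, e.g. `"gap:HTC-HTC"`,
#'   `"chem:HTC->IN"`.  A bare name is matched against both edge sets.
#' @return a modified copy; the input is untouched.
#' @export
ablate <- function(network, what) {
  stopifnot(inherits(network, "thalamic_network"))
  for (w in what) {
    kind <- if (grepl("^gap:", w)) "gap" else if (grepl("^chem:", w)) "chem" else NA
    name <- sub("^(gap|chem):", "", w)
    hit <- FALSE
    if (is.na(kind) || kind == "gap") {
      sel <- network$gap$pathway == name
      if (any(sel)) { network$gap <- network$gap[!sel, ]; hit <- TRUE }
    }
    if (is.na(kind) || kind == "chem") {
      sel <- network$chem$pathway == name
      if (any(sel)) { network$chem <- network$chem[!sel, ]; hit <- TRUE }
    }
    if (!hit) stop("unknown pathway: ", w)
  }
  network
}

#' Override a synaptic weight or STD flag on named pathways
#'
#' @param network a [build_network()] result.
#' @param pathway pathway name or vector of names (e.g. `"RE->HTC"`), or the
#'   shorthand `"RE->TC"` which expands to both RE->HTC and RE->RTC, and
#'   `"TC->RE"` to HTC->RE and RTC->RE.
#' @param g_ampa,g_nmda,g_gaba new conductances in nS (NULL = keep).
#' @param std set to `FALSE` to clamp the depression variable at 1 on the
#'   pathway.
#' @return a modified copy.
#' @export
reweight <- function(network, pathway, g_ampa = NULL, g_nmda = NULL,
                     g_gaba = NULL, std = NULL) {
  stopifnot(inherits(network, "thalamic_network"))
  expand <- function(p) switch(p,
    "RE->TC" = c("RE->HTC", "RE->RTC"),
    "TC->RE" = c("HTC->RE", "RTC->RE"), p)
  pw <- unlist(lapply(pathway, expand))
  sel <- network$chem$pathway %in% pw
  if (!any(sel)) stop("unknown pathway: ", paste(pathway, collapse = ", "))
  if (!is.null(g_ampa)) network$chem$g_ampa[sel] <- g_ampa
  if (!is.null(g_nmda)) network$chem$g_nmda[sel] <- g_nmda
  if (!is.null(g_gaba)) network$chem$g_gaba[sel] <- g_gaba
  if (!is.null(std)) network$chem$std[sel] <- std
  network
}

#' Export / import the edge lists as delimited text
#'
#' @param network a [build_network()] result.
#' @param file path to a tab-separated file.
#' @return `write_edges` returns the file path invisibly; `read_edges`
#'   returns a list with `chem` and `gap` data frames.
#' @export
write_edges <- function(network, file) {
  chem <- cbind(kind = "chem", network$chem[, c("pathway", "pre", "post")],
                weight = ifelse(network$chem$g_gaba > 0, network$chem$g_gaba,
                                network$chem$g_ampa))
  gap <- cbind(kind = "gap",
               data.frame(pathway = network$gap$pathway,
                          pre = network$gap$a, post = network$gap$b,
                          weight = network$gap$R_g))
  write.table(rbind(chem, gap), file, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(file)
}

#' @rdname write_edges
#' @export
read_edges <- function(file) {
  x <- read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  list(chem = x[x$kind == "chem", -1], gap = x[x$kind == "gap", -1])
}
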
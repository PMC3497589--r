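# Independent geometry oracle: a basis with c along Cartesian z and b in
# the yz plane (a different convention from the package's orthogonalization,
# so shared formula errors cannot cancel).  Both conventions are
# right-handed, so signed torsions must agree too.
oracle_basis <- function(cell) {
  d2r <- function(x) x * pi / 180
  ca <- cos(d2r(cell$alpha)); cb <- cos(d2r(cell$beta))
  cg <- cos(d2r(cell$gamma)); sa <- sin(d2r(cell$alpha))
  cvec <- c(0, 0, cell$c)
  bvec <- c(0, cell$b * sa, cell$b * ca)
  az <- cell$a * cb
  ay <- cell$a * (cg - cb * ca) / sa
  ax <- sqrt(cell$a^2 - ay^2 - az^2)
  rbind(a = c(ax, ay, az), b = bvec, c = cvec)
}

oracle_cart <- function(cell, x) drop(x %*% oracle_basis(cell))

oracle_volume <- function(cell) {
  B <- oracle_basis(cell)
  abs(det(B))
}

xprod <- function(u, v) c(u[2]*v[3]-u[3]*v[2], u[3]*v[1]-u[1]*v[3],
                          u[1]*v[2]-u[2]*v[1])

oracle_distance <- function(cell, x1, x2)
  sqrt(sum((oracle_cart(cell, x2) - oracle_cart(cell, x1))^2))

oracle_angle <- function(cell, x1, x2, x3) {
  u <- oracle_cart(cell, x1) - oracle_cart(cell, x2)
  v <- oracle_cart(cell, x3) - oracle_cart(cell, x2)
  acos(sum(u*v) / sqrt(sum(u*u) * sum(v*v))) * 180 / pi
}

oracle_torsion <- function(cell, x1, x2, x3, x4) {
  p <- lapply(list(x1, x2, x3, x4), function(x) oracle_cart(cell, x))
  b1 <- p[[2]] - p[[1]]; b2 <- p[[3]] - p[[2]]; b3 <- p[[4]] - p[[3]]
  n1 <- xprod(b1, b2); n2 <- xprod(b2, b3)
  atan2(sum(xprod(n1, n2) * b2 / sqrt(sum(b2*b2))), sum(n1 * n2)) * 180 / pi
}

random_cell <- function() {
  repeat {
    cl <- try(unit_cell(runif(1, 3, 15), runif(1, 3, 15), runif(1, 3, 15),
                        runif(1, 60, 120), runif(1, 60, 120),
                        runif(1, 60, 120)), silent = TRUE)
    if (!inherits(cl, "try-error")) return(cl)
  }
}

# random CIF value within the writer's representable set
random_value <- function() {
  pick <- sample(8, 1)
  if (pick == 1) return(cif_value(format(round(runif(1, -500, 500), 3))))
  if (pick == 2) return(cif_value(sprintf("%.3f(%d)", runif(1, 0, 99),
                                          sample(9, 1))))
  if (pick == 3) return(cif_value("?"))
  if (pick == 4) return(cif_value("."))
  if (pick == 5) return(cif_value(paste(sample(letters, 3), collapse = "")))
  if (pick == 6) return(cif_value(paste(sample(c(letters, " ", "'"),
                                               8, replace = TRUE),
                                        collapse = ""), quoted = TRUE))
  if (pick == 7) return(cif_value("12.5", quoted = TRUE))  # number-like string
  cif_value(paste("line one of a text block,",
                  "line two", sep = "\n"), textblock = TRUE)
}

random_document <- function(seed) {
  set.seed(seed)
  nb <- sample(1:3, 1)
  blocks <- lapply(seq_len(nb), function(bi) {
    nitems <- sample(0:6, 1)
    items <- list()
    for (i in seq_len(nitems))
      items[[sprintf("_item_%d_%d", bi, i)]] <- random_value()
    nloops <- sample(0:2, 1)
    loops <- lapply(seq_len(nloops), function(li) {
      ncol <- sample(1:3, 1)
      nrow <- sample(1:4, 1)
      tags <- sprintf("_loop%d_%d_col%d", bi, li, seq_len(ncol))
      rows <- lapply(seq_len(nrow), function(r)
        lapply(seq_len(ncol), function(cc) random_value()))
      cif_loop(tags, rows)
    })
    cif_block(sprintf("block_%d_%d", seed, bi), items, loops)
  })
  cif_document(blocks)
}

# standard small operator sets for orbit tests
op_sets <- function() {
  list(
    P1 = list(parse_symop("x,y,z")),
    `P-1` = lapply(c("x,y,z", "-x,-y,-z"), parse_symop),
    P21 = lapply(c("x,y,z", "-x,y+1/2,-z"), parse_symop),
    `P21/c` = lapply(c("x,y,z", "-x,y+1/2,-z+1/2",
                       "-x,-y,-z", "x,-y+1/2,z+1/2"), parse_symop))
}

# independent orbit count: all images, wrapped mod 1 and deduplicated by
# rounding to 1e-6 (valid for generic positions and exact special ones)
oracle_orbit_size <- function(ops, x) {
  imgs <- t(vapply(ops, function(op)
    (drop(op$rot %*% x) + op$trans) %% 1, numeric(3)))
  key <- apply(round(imgs * 1e6) %% 1e6, 1, paste, collapse = ",")
  length(unique(key))
}

# independent bond oracle: all pairs, all 27 neighbour shifts, oracle basis
oracle_bond_set <- function(cell, sites, radii, tol) {
  B <- oracle_basis(cell)
  n <- length(sites)
  out <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    si <- sites[[i]]; sj <- sites[[j]]
    gi <- si$disorder_group; gj <- sj$disorder_group
    if (!is.na(gi) && !is.na(gj) && gi != gj) {
      ai <- si$disorder_assembly; aj <- sj$disorder_assembly
      same_asm <- (is.na(ai) && is.na(aj)) ||
        (!is.na(ai) && !is.na(aj) && ai == aj)
      if (same_asm) next
    }
    dmin <- Inf
    for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
      d <- drop((si$frac - sj$frac + c(sx, sy, sz)) %*% B)
      dmin <- min(dmin, sqrt(sum(d * d)))
    }
    if (dmin <= radii[[si$element]] + radii[[sj$element]] + tol)
      out <- c(out, paste(sort(c(si$label, sj$label)), collapse = "|"))
  }
  sort(out)
}

bond_key_set <- function(graph)
  sort(vapply(graph$bonds, function(b)
    paste(sort(c(b$atom1, b$atom2)), collapse = "|"), ""))

serious_alerts <- function(report)
  Filter(function(a) a$severity %in% c("A", "B"), report$alerts)
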
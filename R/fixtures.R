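# Deterministic toy-complex geometries with known ground truth: the
# package's desk-scale stand-in for curated TMC datasets. All coordinates
# are pure arithmetic (no randomness) at typical bond lengths, and every
# fixture carries the expected ligand charges, oxidation state and -- for
# the regression-pinned cases -- the expected canonical SMILES.

# rotation taking (0,0,1) onto the unit vector u
.rotZTo <- function(u) {
  u <- u / sqrt(sum(u^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * u[3] - z[3] * u[2],
         z[3] * u[1] - z[1] * u[3],
         z[1] * u[2] - z[2] * u[1])
  c0 <- sum(z * u)
  if (abs(c0 + 1) < 1e-12) return(diag(c(1, -1, -1)))  # u = -z
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c0)
}

# add a 3-vector offset to every row of a coordinate matrix
.offsetRows <- function(mat, vec) sweep(mat, 2, vec, "+")

# three unit directions at the tetrahedral angle from `axis`, azimuths
# offset by `phi0` degrees
.tetraDirs <- function(axis, phi0 = 90) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  t(vapply(phi0 + c(0, 120, 240), function(phi) {
    p <- phi * pi / 180
    -axis / 3 + sqrt(8) / 3 * (cos(p) * e1 + sin(p) * e2)
  }, numeric(3)))
}

# ligand templates: donor atom at the origin, ligand body extending toward
# +z (the metal sits on the -z side); returns list(elements, coords)
.tmplMonatomic <- function(el) list(elements = el,
                                    coords = matrix(0, 1, 3))

.tmplNH3 <- function() {
  dirs <- .tetraDirs(c(0, 0, -1), phi0 = 0)
  list(elements = c("N", "H", "H", "H"),
       coords = rbind(c(0, 0, 0), 1.01 * dirs))
}

.tmplCO <- function() list(elements = c("C", "O"),
                           coords = rbind(c(0, 0, 0), c(0, 0, 1.14)))

.tmplPyridine <- function(nitro = FALSE) {
  centroid <- c(0, 0, 1.39)
  vert <- function(phi) centroid +
    1.39 * c(sin(phi * pi / 180), 0, -cos(phi * pi / 180))
  els <- c("N", "C", "C", "C", "C", "C")
  xyz <- t(vapply(c(0, 60, 120, 180, 240, 300), vert, numeric(3)))
  coords <- xyz
  elements <- els
  for (k in 2:6) {
    pos <- xyz[k, ]
    if (nitro && k == 4L) {       # para carbon carries the nitro group
      u <- (pos - centroid) / 1.39
      nN <- pos + 1.47 * u
      perp <- c(u[3], 0, -u[1])   # in-plane normal to the radial axis
      o1 <- nN + 1.22 * (cos(pi / 3) * u + sin(pi / 3) * perp)
      o2 <- nN + 1.22 * (cos(pi / 3) * u - sin(pi / 3) * perp)
      elements <- c(elements, "N", "O", "O")
      coords <- rbind(coords, nN, o1, o2)
    } else {
      h <- pos + 1.08 * (pos - centroid) / 1.39
      elements <- c(elements, "H")
      coords <- rbind(coords, h)
    }
  }
  list(elements = elements, coords = coords)
}

.tmplAcetate <- function() {
  o1 <- c(0, 0, 0)
  c1 <- c(0, 0, 1.28)
  o2 <- c1 + 1.23 * c(-sin(pi / 3), 0, cos(pi / 3))
  c2 <- c1 + 1.50 * c(sin(pi / 3), 0, cos(pi / 3))
  hs <- .offsetRows(1.09 * .tetraDirs(c1 - c2), c2)
  list(elements = c("O", "C", "O", "C", "H", "H", "H"),
       coords = rbind(o1, c1, o2, c2, hs))
}

.tmplMesylate <- function() {
  o1 <- c(0, 0, 0)
  s <- c(0, 0, 1.48)
  dirs <- .tetraDirs(c(0, 0, -1), phi0 = 0)
  o2 <- s + 1.44 * dirs[1, ]
  o3 <- s + 1.44 * dirs[2, ]
  cc <- s + 1.80 * dirs[3, ]
  hs <- .offsetRows(1.09 * .tetraDirs(s - cc), cc)
  list(elements = c("O", "S", "O", "O", "C", "H", "H", "H"),
       coords = rbind(o1, s, o2, o3, cc, hs))
}

.tmplNHC <- function() {
  r <- 1.37 / (2 * sin(pi / 5))
  centroid <- c(0, 0, r)
  vert <- function(phi) centroid +
    r * c(sin(phi * pi / 180), 0, -cos(phi * pi / 180))
  # ring: C2 (carbene, donor), N1, C5, C4, N3
  xyz <- t(vapply(c(0, 72, 144, 216, 288), vert, numeric(3)))
  elements <- c("C", "N", "C", "C", "N")
  coords <- xyz
  for (k in c(2L, 5L)) {          # N-methyl groups
    u <- (xyz[k, ] - centroid) / r
    me <- xyz[k, ] + 1.47 * u
    hs <- .offsetRows(1.09 * .tetraDirs(xyz[k, ] - me), me)
    elements <- c(elements, "C", "H", "H", "H")
    coords <- rbind(coords, me, hs)
  }
  for (k in c(3L, 4L)) {          # ring C-H
    u <- (xyz[k, ] - centroid) / r
    elements <- c(elements, "H")
    coords <- rbind(coords, xyz[k, ] + 1.08 * u)
  }
  list(elements = elements, coords = coords)
}

.tmplPerchlorate <- function() {
  o1 <- c(0, 0, 0)
  cl <- 1.50 * c(sin(50 * pi / 180), 0, cos(50 * pi / 180))
  u <- cl / sqrt(sum(cl^2))
  dirs <- .tetraDirs(-u, phi0 = 90)   # terminal O's point away from O1
  os <- .offsetRows(1.43 * dirs, cl)
  list(elements = c("O", "Cl", "O", "O", "O"),
       coords = rbind(o1, cl, os))
}

# place a template with its donor atom at distance `dist` from the metal
# (at `origin`) along unit direction `u`
.placeLigand <- function(tmpl, u, dist, origin = c(0, 0, 0)) {
  u <- u / sqrt(sum(u^2))
  R <- .rotZTo(u)
  anchor <- origin + dist * u
  coords <- t(R %*% t(tmpl$coords)) + rep(anchor, each = nrow(tmpl$coords))
  list(elements = tmpl$elements, coords = coords)
}

.buildComplex <- function(metal, placed) {
  elements <- metal
  coords <- matrix(0, 1, 3)
  for (p in placed) {
    elements <- c(elements, p$elements)
    coords <- rbind(coords, p$coords)
  }
  new("XYZStructure", elements = elements, coords = coords)
}

.octDirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))

# the bidentate fixtures have bespoke coordinates (planar chelates)
.buildBipyNickel <- function() {
  centroidA <- c(2.135, 0, 0)
  vert <- function(phi) centroidA +
    1.39 * c(cos(phi * pi / 180), sin(phi * pi / 180), 0)
  ringA <- t(vapply(c(180, 120, 60, 0, 300, 240), vert, numeric(3)))
  elsA <- c("C", "N", "C", "C", "C", "C")   # C2a, N1, C6a, C5a, C4a, C3a
  hA <- t(vapply(3:6, function(k) {
    ringA[k, ] + 1.08 * (ringA[k, ] - centroidA) / 1.39
  }, numeric(3)))
  mirror <- function(x) cbind(-x[, 1, drop = FALSE], x[, 2, drop = FALSE],
                              x[, 3, drop = FALSE])
  elements <- c("Ni", elsA, rep("H", 4), elsA, rep("H", 4), "Cl", "Cl")
  coords <- rbind(c(0, 2.663, 0),
                  ringA, hA, mirror(ringA), mirror(hA),
                  c(1.591, 4.254, 0), c(-1.591, 4.254, 0))
  new("XYZStructure", elements = elements, coords = coords)
}

.buildAcacCobalt <- function() {
  o1 <- c(1.95, 0, 0); o2 <- c(0, 1.95, 0)
  c1 <- c(2.77, 0.969, 0); c3 <- c(0.969, 2.77, 0)
  c2 <- c(2.263, 2.263, 0)
  u4 <- c(0.971, -0.238, 0)
  c4 <- c1 + 1.50 * u4
  c5 <- c(c4[2], c4[1], 0)
  h2 <- c2 + 1.09 * c(sqrt(0.5), sqrt(0.5), 0)
  h4 <- .offsetRows(1.09 * .tetraDirs(c1 - c4), c4)
  h5 <- h4[, c(2, 1, 3)]
  nh3 <- lapply(list(c(-1, 0, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
                function(u) .placeLigand(.tmplNH3(), u, 1.96))
  acac <- list(elements = c("O", "O", "C", "C", "C", "C", "C",
                            "H", "H", "H", "H", "H", "H", "H"),
               coords = rbind(o1, o2, c1, c3, c2, c4, c5,
                              h2, h4, h5))
  .buildComplex("Co", c(list(acac), nh3))
}

.buildFakeHapticZr <- function() {
  # methanimine H2C=NH bound through N at 2.0 A; its sp2 carbon sits at
  # 2.9 A from the metal -- inside the distance criterion (cutoff 2.96 A)
  # but 1.45 times the N distance, i.e. a spurious haptic bond. The carbon
  # has exactly four neighbors, so valence trimming leaves the fake bond
  # for the haptic pruner.
  n <- c(0, 0, 2.0)
  cc <- c(1.0763, 0, 2.6929)
  hN <- n + 1.01 * c(-0.60, 0, 0.80)
  hC1 <- cc + 1.09 * c(0.4205, 0.866, 0.2705)
  hC2 <- cc + 1.09 * c(0.4205, -0.866, 0.2705)
  cls <- lapply(list(c(0.985, 0, -0.174), c(-0.985, 0, -0.174),
                     c(0, 0.985, -0.174), c(0, -0.985, -0.174)),
                function(u) .placeLigand(.tmplMonatomic("Cl"), u, 2.44))
  imine <- list(elements = c("N", "C", "H", "H", "H"),
                coords = rbind(n, cc, hN, hC1, hC2))
  .buildComplex("Zr", c(list(imine), cls))
}

.buildCpManganese <- function() {
  r <- 1.42 / (2 * sin(pi / 5))
  z <- sqrt(2.15^2 - r^2)
  ring <- t(vapply(72 * (0:4), function(phi) {
    p <- phi * pi / 180
    c(r * cos(p), r * sin(p), z)
  }, numeric(3)))
  hs <- t(vapply(72 * (0:4), function(phi) {
    p <- phi * pi / 180
    c((r + 1.08) * cos(p), (r + 1.08) * sin(p), z)
  }, numeric(3)))
  cp <- list(elements = c(rep("C", 5), rep("H", 5)),
             coords = rbind(ring, hs))
  cos125 <- cos(125 * pi / 180); sin125 <- sin(125 * pi / 180)
  carbonyls <- lapply(c(90, 210, 330), function(phi) {
    p <- phi * pi / 180
    u <- c(sin125 * cos(p), sin125 * sin(p), cos125)
    .placeLigand(.tmplCO(), u, 1.80)
  })
  .buildComplex("Mn", c(list(cp), carbonyls))
}

.buildBoraneChromium <- function() {
  a <- 1.72 / sqrt(2)
  bs <- rbind(c(a, 0, 0), c(-a, 0, 0), c(0, a, 0), c(0, -a, 0),
              c(0, 0, a), c(0, 0, -a))
  hs <- bs * (a + 1.19) / a
  cage <- list(elements = c(rep("B", 6), rep("H", 6)),
               coords = rbind(bs, hs) - rep(c(2.2, 0, 2.2),
                                            each = 12))
  # metal at the origin; cage shifted so Cr sits 2.41 A from two B vertices
  .buildComplex("Cr", list(cage))
}

# Regression-pinned canonical SMILES, fixed from the pipeline's output on
# the idealized geometries after manual verification of ligand charges,
# oxidation states and Lewis structures. Geometry or rule changes that
# alter any of these strings are breaking changes.
.pinnedSmiles <- c(
  hexaammine_cobalt3 = "[Co+3](<-N)(<-N)(<-N)(<-N)(<-N)<-N",
  tetrachloro_platinum2 = "[Cl-]->[Pt+2](<-[Cl-])(<-[Cl-])<-[Cl-]",
  hexacarbonyl_chromium0 = "[Cr](<-[C-]#[O+])(<-[C-]#[O+])(<-[C-]#[O+])(<-[C-]#[O+])(<-[C-]#[O+])<-[C-]#[O+]",
  pentaammine_chloro_cobalt3 = "[Cl-]->[Co+3](<-N)(<-N)(<-N)(<-N)<-N",
  pyridine_ruthenium2 = "C1=CN(=CC=C1)->[Ru+2](<-N)(<-N)(<-N)(<-N)<-N",
  nitropyridine_ruthenium2 = "C=1(C=CN(=CC=1)->[Ru+4](<-N)(<-N)(<-N)(<-N)<-N)N([O-])[O-]",
  acetato_cobalt3 = "[Co+3](<-N)(<-N)(<-N)(<-N)(<-N)<-[O-]C(C)=O",
  mesylate_cobalt3 = "[Co+3](<-N)(<-N)(<-N)(<-N)(<-N)<-[O-]S(C)(=O)=O",
  nhc_silver1 = "[Ag+](<-[Cl-])<-[C]1N(C=CN1C)C",
  bipyridine_nickel2 = "[Cl-]->[Ni+2]<-1(<-[Cl-])<-N=2C(C3=CC=CC=N->13)=CC=CC=2",
  acac_cobalt3 = "[Co+3]<-1(<-N)(<-N)(<-N)(<-N)<-[O-]C(=CC(C)=O->1)C",
  fake_haptic_zirconium4 = "[Cl-]->[Zr+4](<-[Cl-])(<-[Cl-])(<-[Cl-])<-N=C",
  cp_manganese1 = "[C-](->[Mn+]<-1<-2<-3<-4(<-[C-]#[O+])(<-[C-]#[O+])<-[CH-]5C->1=C->2C->3=C->45)#[O+]",
  perchlorate_cobalt = "Cl[O-].Cl[O-].[Co+15](<-N)(<-N)(<-N)(<-N)(<-[O-2])<-[O-2].[O-2].[O-2].[O-2].[O-2]")

#' Build one toy-complex fixture
#'
#' Generates the deterministic xyz geometry and the paired expected record
#' for one named fixture. Supported recipes cover octahedral, square
#' planar, tetrahedral-like and linear coordination with the ligand set
#' used across the test suite.
#'
#' @param name fixture name (see \code{\link{fixtureSuite}} for the list).
#' @return a list with components \code{name}, \code{xyz} (xyz text),
#'   \code{charge} (Q), and \code{expected} (list with sorted
#'   \code{ligandCharges}, \code{oxidationState}, \code{smiles} or NULL,
#'   \code{failureStage} or NULL, \code{flagged}, and optionally
#'   \code{environments}).
#' @export
makeFixture <- function(name) {
  recipes <- .fixtureRecipes()
  if (!name %in% names(recipes)) stop("unknown fixture recipe: ", name)
  r <- recipes[[name]]
  s <- r$builder()
  expected <- r$expected
  if (name %in% names(.pinnedSmiles))
    expected$smiles <- unname(.pinnedSmiles[name])
  list(name = name, xyz = formatXYZ(s, comment = name), charge = r$charge,
       expected = expected)
}

.fixtureRecipes <- function() {
  oct <- function(tmpls, dists) function() {
    placed <- lapply(seq_along(tmpls), function(k)
      .placeLigand(tmpls[[k]], .octDirs[k, ], dists[k]))
    .buildComplex(attr(tmpls, "metal"), placed)
  }
  withMetal <- function(metal, ...) structure(list(...), metal = metal)
  rep6 <- function(tmpl) replicate(6, tmpl, simplify = FALSE)

  list(
    hexaammine_cobalt3 = list(
      charge = 3L,
      builder = oct(structure(rep6(.tmplNH3()), metal = "Co"), rep(1.96, 6)),
      expected = list(ligandCharges = rep(0L, 6), oxidationState = 3L,
                      flagged = FALSE,
                      environments = rep("N", 6))),
    tetrachloro_platinum2 = list(
      charge = -2L,
      builder = function() {
        placed <- lapply(1:4, function(k)
          .placeLigand(.tmplMonatomic("Cl"), .octDirs[k, ], 2.32))
        .buildComplex("Pt", placed)
      },
      expected = list(ligandCharges = rep(-1L, 4), oxidationState = 2L,
                      flagged = FALSE,
                      environments = rep("Cl", 4))),
    hexacarbonyl_chromium0 = list(
      charge = 0L,
      builder = oct(structure(rep6(.tmplCO()), metal = "Cr"), rep(1.92, 6)),
      expected = list(ligandCharges = rep(0L, 6), oxidationState = 0L,
                      flagged = FALSE,
                      environments = rep("C(O)", 6))),
    pentaammine_chloro_cobalt3 = list(
      charge = 2L,
      builder = oct(structure(c(replicate(5, .tmplNH3(), simplify = FALSE),
                                list(.tmplMonatomic("Cl"))), metal = "Co"),
                    c(rep(1.96, 5), 2.28)),
      expected = list(ligandCharges = c(-1L, rep(0L, 5)),
                      oxidationState = 3L, flagged = FALSE)),
    pyridine_ruthenium2 = list(
      charge = 2L,
      builder = oct(structure(c(replicate(5, .tmplNH3(), simplify = FALSE),
                                list(.tmplPyridine())), metal = "Ru"),
                    c(rep(2.10, 5), 2.08)),
      expected = list(ligandCharges = rep(0L, 6), oxidationState = 2L,
                      flagged = FALSE,
                      environments = c(rep("N", 5), "N(c,c)"))),
    # the frontier rules legitimately assign -2 to 4-nitropyridine (its
    # low-lying pi* sits below the -10.2 eV HOMO threshold once filled);
    # the neutral-ligand reading of the same complex is exercised through
    # the fixed-charge assembly path
    nitropyridine_ruthenium2 = list(
      charge = 2L,
      builder = oct(structure(c(replicate(5, .tmplNH3(), simplify = FALSE),
                                list(.tmplPyridine(nitro = TRUE))),
                              metal = "Ru"),
                    c(rep(2.10, 5), 2.08)),
      expected = list(ligandCharges = c(-2L, rep(0L, 5)),
                      oxidationState = 4L, flagged = FALSE)),
    acetato_cobalt3 = list(
      charge = 2L,
      builder = oct(structure(c(replicate(5, .tmplNH3(), simplify = FALSE),
                                list(.tmplAcetate())), metal = "Co"),
                    c(rep(1.96, 5), 1.93)),
      expected = list(ligandCharges = c(-1L, rep(0L, 5)),
                      oxidationState = 3L, flagged = FALSE)),
    mesylate_cobalt3 = list(
      charge = 2L,
      builder = oct(structure(c(replicate(5, .tmplNH3(), simplify = FALSE),
                                list(.tmplMesylate())), metal = "Co"),
                    c(rep(1.96, 5), 1.93)),
      expected = list(ligandCharges = c(-1L, rep(0L, 5)),
                      oxidationState = 3L, flagged = FALSE)),
    nhc_silver1 = list(
      charge = 0L,
      builder = function() {
        nhc <- .placeLigand(.tmplNHC(), c(0, 0, 1), 2.10)
        cl <- .placeLigand(.tmplMonatomic("Cl"), c(0, 0, -1), 2.30)
        .buildComplex("Ag", list(nhc, cl))
      },
      expected = list(ligandCharges = c(-1L, 0L), oxidationState = 1L,
                      flagged = FALSE,
                      environments = c("C(n,n)", "Cl"))),
    bipyridine_nickel2 = list(
      charge = 0L,
      builder = .buildBipyNickel,
      expected = list(ligandCharges = c(-1L, -1L, 0L),
                      oxidationState = 2L, flagged = FALSE,
                      environments = c("Cl", "Cl", "N(c,c)", "N(c,c)"))),
    acac_cobalt3 = list(
      charge = 2L,
      builder = .buildAcacCobalt,
      expected = list(ligandCharges = c(-1L, rep(0L, 4)),
                      oxidationState = 3L, flagged = FALSE)),
    fake_haptic_zirconium4 = list(
      charge = 0L,
      builder = .buildFakeHapticZr,
      expected = list(ligandCharges = c(rep(-1L, 4), 0L),
                      oxidationState = 4L, flagged = FALSE)),
    cp_manganese1 = list(
      charge = 0L,
      builder = .buildCpManganese,
      expected = list(ligandCharges = c(-1L, 0L, 0L, 0L),
                      oxidationState = 1L, flagged = FALSE,
                      environments = c(rep("C(c,c)", 5), rep("C(O)", 3)))),
    perchlorate_cobalt = list(
      charge = 1L,
      builder = function() {
        placed <- c(
          lapply(list(c(0, 0, 1), c(1, 0, 0)), function(u)
            .placeLigand(.tmplPerchlorate(), u, 1.93)),
          lapply(list(c(0, 0, -1), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)),
                 function(u) .placeLigand(.tmplNH3(), u, 1.96)))
        .buildComplex("Co", placed)
      },
      expected = list(oxidationState = 15L, flagged = TRUE)),
    borane_chromium = list(
      charge = 0L,
      builder = .buildBoraneChromium,
      expected = list(failureStage = "ligand_lewis")))
}

#' The full fixture suite
#'
#' Builds all toy complexes: neutral sigma-donors (ammine, carbonyl,
#' pyridine), anionic ligands (chloride, acetate, mesylate), bidentates
#' (bipyridine, acetylacetonate), an N-heterocyclic carbene, a nitro-group
#' ligand, a spurious-haptic geometry, a genuine eta-5 cyclopentadienyl, a
#' perchlorate artifact (stranded oxygens, inflated oxidation state) and a
#' borane cage (expected failure at the Lewis stage).
#'
#' @return a list of fixtures as returned by \code{\link{makeFixture}}.
#' @export
fixtureSuite <- function() {
  lapply(names(.fixtureRecipes()), makeFixture)
}

#' Write the fixture suite to a directory
#'
#' Writes one xyz file per fixture plus an \code{expected.tsv} table with
#' the overall charge, expected oxidation state and expected outcome.
#'
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeFixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  suite <- fixtureSuite()
  rows <- lapply(suite, function(fx) {
    writeLines(fx$xyz, file.path(dir, paste0(fx$name, ".xyz")))
    data.frame(name = fx$name, charge = fx$charge,
               oxidationState = if (is.null(fx$expected$oxidationState))
                 NA_integer_ else fx$expected$oxidationState,
               expectedOutcome = if (is.null(fx$expected$failureStage))
                 "OK" else paste0("FAILED:", fx$expected$failureStage))
  })
  utils::write.table(do.call(rbind, rows),
                     file.path(dir, "expected.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
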
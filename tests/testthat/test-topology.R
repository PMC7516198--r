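test_that("hexagonal lattice interiors are six-sided", {
  # lattice overflows the bounds so every ragged-edge cell is excluded
  pts <- hexLattice(14, 14, pitch = 10)
  topo <- voronoiTopology(pts, width = 120, height = 105)
  df <- cellData(topo)
  expect_true(all(df$sideCount[!df$excluded] == 6))
  expect_gt(sum(!df$excluded), 50)
  expect_equal(polygonDistribution(topo), c("4" = 0, "5" = 0, "6" = 1,
                                            "7" = 0, "8" = 0, "9+" = 0))
})

test_that("zero-length ridges of co-circular lattices create no adjacency", {
  g <- expand.grid(x = 0:6, y = 0:6)
  topo <- voronoiTopology(cbind(g$x, g$y), width = 7, height = 7)
  df <- cellData(topo)
  ctr <- which(g$x == 3 & g$y == 3)
  expect_false(df$excluded[ctr])
  expect_equal(df$sideCount[ctr], 4L)
  expect_setequal(neighbourIds(topo)[[ctr]],
                  which((abs(g$x - 3) + abs(g$y - 3)) == 1))
})

test_that("voronoi adjacency matches the half-plane-intersection oracle", {
  set.seed(57)
  for (i in 1:4) {
    n <- sample(10:30, 1)
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 80))
    topo <- voronoiTopology(pts, width = 101, height = 81)
    want <- oracleVoronoiAdjacency(pts, -0.5, -0.5, 100.5, 80.5)
    got <- neighbourIds(topo)
    for (k in seq_len(n)) expect_equal(got[[k]], want[[k]])
  }
})

test_that("the neighbour relation is symmetric and sized consistently", {
  pts <- generateMonolayer(monolayerSpec(256, 256, 300, 8, 3, seed = 14))
  topo <- voronoiTopology(pts)
  nb <- neighbourIds(topo)
  df <- cellData(topo)
  for (i in seq_along(nb)) {
    for (j in nb[[i]]) expect_true(i %in% nb[[j]])
    if (!df$excluded[i]) expect_equal(df$sideCount[i], length(nb[[i]]))
  }
})

test_that("voronoi cell areas partition the image", {
  pts <- coords(generateMonolayer(monolayerSpec(128, 128, 150, 8, 3,
                                                seed = 8)))
  cells <- scratchTopo:::cpp_voronoi_cells(pts, -0.5, -0.5, 127.5, 127.5,
                                           1e-6)
  total <- sum(vapply(cells, function(cl) cl$area, 0))
  expect_equal(total, 128 * 128, tolerance = 1e-8)
})

test_that("degenerate point sets are rejected", {
  expect_error(voronoiTopology(cbind(1:3, 1:3), width = 10, height = 10),
               "4 points")
  expect_error(voronoiTopology(cbind(1:5, 2 * (1:5)), width = 20,
                               height = 20), "collinear")
})

test_that("polygon frequencies match a manual count", {
  sides <- c(5, 6, 6, 7, 6, 5, 4, 6, 8, 6)
  df <- data.frame(id = 1:10, x = runif(10), y = runif(10),
                   sideCount = sides, area = 1, excluded = FALSE)
  df$polygonClass <- as.character(sides)
  tab <- new("TopologyTable", cells = df,
             neighbours = replicate(10, integer(0), simplify = FALSE))
  freq <- polygonDistribution(tab)
  expect_equal(sum(freq), 1)
  expect_equal(unname(freq[c("4", "5", "6", "7", "8")]),
               c(1, 2, 5, 1, 1) / 10)
})

test_that("expected co-occurrence is side count times class frequency", {
  f <- c(tetragon = 0.07, pentagon = 0.29, hexagon = 0.36, heptagon = 0.20,
         octagon = 0.06)
  M <- expectedCooccurrence(f)
  expect_equal(M["hexagon", "hexagon"], 2.16)
  expect_equal(M["heptagon", "hexagon"], 2.52)
  expect_equal(suppressWarnings(
    expectedCooccurrence(c(hexagon = 0.36, nonagon = 0)))[
      "hexagon", "nonagon"], 0)
  # rows sum to the focal side count when frequencies sum to 1
  f2 <- c(tetragon = 0.1, pentagon = 0.3, hexagon = 0.4, heptagon = 0.2)
  expect_equal(unname(rowSums(expectedCooccurrence(f2))), c(4, 5, 6, 7))
  expect_warning(expectedCooccurrence(c(hexagon = 0.2)), "sum")
})

test_that("observed co-occurrence matches exhaustive per-cell counting", {
  # all-hexagon lattice: a hexagon shares 6 sides with hexagons, surely
  topo <- voronoiTopology(hexLattice(14, 14, 10), width = 120, height = 105)
  obs <- observedCooccurrence(topo)
  expect_named(obs, "6")
  expect_equal(unname(obs[["6"]]["6", "6"]), 1)
  expect_true(all(abs(rowSums(obs[["6"]]) - 1) < 1e-12))

  # random labelling, independent recount
  set.seed(77)
  n <- 30
  adj <- vector("list", n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) if (runif(1) < 0.15) {
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  classes <- sample(c("4", "5", "6", "7"), n, replace = TRUE)
  df <- data.frame(id = 1:n, x = runif(n), y = runif(n),
                   sideCount = as.integer(classes), area = 1,
                   excluded = FALSE, polygonClass = classes)
  tab <- new("TopologyTable", cells = df, neighbours = adj)
  obs <- observedCooccurrence(tab)
  for (fc in unique(classes)) for (cc in c("4", "5", "6", "7")) {
    focal <- which(classes == fc)
    ks <- vapply(focal, function(i) sum(classes[adj[[i]]] == cc), 0)
    want <- tabulate(ks + 1, nbins = ncol(obs[[fc]])) / length(focal)
    expect_equal(unname(obs[[fc]][cc, ]), want)
  }
})

test_that("LCD is the inverse k-th neighbour distance with its symmetries", {
  expect_equal(localCellDensity(rbind(c(0, 0), c(4, 0)), k = 1), c(0.25, 0.25))

  # unit lattice: cumulative neighbour counts reach 36 at squared radius 10
  g <- as.matrix(expand.grid(x = 0:24, y = 0:24))
  lcd <- localCellDensity(g, k = 36)
  ctr <- which(g[, "x"] %in% 10:14 & g[, "y"] %in% 10:14)
  expect_equal(lcd[ctr], rep(1 / sqrt(10), length(ctr)))

  set.seed(3)
  pts <- cbind(runif(60, 0, 50), runif(60, 0, 50))
  base <- localCellDensity(pts, k = 5)
  expect_equal(localCellDensity(pts * 2.5, k = 5), base / 2.5)
  expect_equal(localCellDensity(sweep(pts, 2, c(7, -3), "+"), k = 5), base)
  expect_error(localCellDensity(pts, k = 60), "insufficient")
})

test_that("normalised LCD divides by wound distance", {
  expect_equal(normalisedLCD(0.2, 100), 0.002)
  lcd <- runif(10, 0.1, 0.3); d <- runif(10, 50, 150)
  expect_equal(normalisedLCD(lcd, 2 * d), normalisedLCD(lcd, d) / 2)
  expect_equal(normalisedLCD(lcd, d), lcd / d)
  expect_warning(out <- normalisedLCD(c(0.1, 0.2), c(0, 5)), "zero")
  expect_true(is.na(out[1]))
})

test_that("LCD-distance correlation behaves at the extremes", {
  d <- seq(10, 200, length.out = 30)
  expect_equal(lcdDistanceCorrelation(0.001 + 0.002 * d, d), 1)
  expect_equal(lcdDistanceCorrelation(1 - 0.002 * d, d), -1)
  expect_error(lcdDistanceCorrelation(rep(1, 10), 1:10), "constant")
})

test_that("larger synthetic cells have more sides (Lewis' law direction)", {
  pts <- generateMonolayer(monolayerSpec(512, 512, 1500, 8, 4, seed = 25))
  df <- cellData(voronoiTopology(pts))
  inc <- !df$excluded
  expect_gt(stats::cor(df$area[inc], df$sideCount[inc]), 0)
})
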
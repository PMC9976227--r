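test_that("load_trade_flows validates, aggregates and logs rejections", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("year,exporter_iso3,importer_iso3,value_usd",
               "2019,AAA,BBB,60e6",
               "2019,AAA,BBB,50e6",
               "2019,AAA,CCC,2e8",
               "2019,BBB,CCC,1e7",
               "2019,DDD,DDD,5e6",
               "2019,EEE,FFF,-1"), csv)
  fl <- load_trade_flows(csv)
  expect_s3_class(fl, "trade_flows")
  expect_equal(nrow(fl), 3L)
  expect_equal(fl$value[fl$exporter == "AAA" & fl$importer == "BBB"], 110e6)
  rep <- attr(fl, "validation")
  expect_equal(rep$rows_in, 6L)
  expect_setequal(rep$rejected$reason, c("self-flow", "negative value"))
  expect_equal(nrow(rep$rejected), 2L)

  # missing column is a configuration error
  bad <- tempfile(fileext = ".csv")
  writeLines(c("year,exporter_iso3,importer_iso3", "2019,AAA,BBB"), bad)
  expect_error(load_trade_flows(bad), "columns not found")

  # custom column map
  csv2 <- tempfile(fileext = ".csv")
  writeLines(c("yr,from,to,usd", "2019,aaa,bbb,100"), csv2)
  fl2 <- load_trade_flows(csv2, column_map = c(year = "yr", exporter = "from",
                                               importer = "to", value = "usd"))
  expect_equal(fl2$exporter, "AAA")
})

test_that("unknown country codes are kept but flagged", {
  fl <- trade_flows(data.frame(year = 2019, exporter = c("CHN", "QQQ"),
                               importer = "RUS", value = 1),
                    known_codes = c("CHN", "RUS"))
  expect_equal(nrow(fl), 2L)
  expect_equal(attr(fl, "validation")$unknown_codes, "QQQ")
})

test_that("build_network lays flows out as exporter rows x importer columns", {
  fl <- flows_from_edges(data.frame(exporter = "AAA", importer = "BBB",
                                    value = 2e8))
  net <- build_network(fl, 2019)
  expect_equal(net$nodes, c("AAA", "BBB"))
  expect_equal(net$weights["AAA", "BBB"], 2e8)
  expect_equal(sum(net$weights), 2e8)

  # restriction fills absent pairs with zero
  net3 <- build_network(fl, 2019, countries = c("AAA", "BBB", "CCC"))
  expect_equal(dim(net3$weights), c(3L, 3L))
  expect_true(all(net3$weights["CCC", ] == 0) &&
                all(net3$weights[, "CCC"] == 0))

  expect_error(build_network(fl, 1999), "no flows")
})

test_that("aggregation conserves total value into the matrix", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    codes <- sprintf("C%02d", seq_len(n))
    m <- sample(10:40, 1)
    df <- data.frame(year = 2019,
                     exporter = sample(codes, m, replace = TRUE),
                     importer = sample(codes, m, replace = TRUE),
                     value = runif(m, 1e6, 5e8))
    fl <- trade_flows(df)
    net <- build_network(fl, 2019, countries = codes)
    expect_equal(sum(net$weights), sum(fl$value))
  }
})

test_that("binarize: inclusive threshold, idempotence, monotone edge count", {
  fl <- flows_from_edges(data.frame(
    exporter = c("AAA", "AAA", "BBB"), importer = c("BBB", "CCC", "CCC"),
    value = c(99999999, 1e8, 3e8)))
  net <- binarize(build_network(fl, 2019), 1e8)
  expect_equal(net$binary["AAA", "BBB"], 0L)  # just below
  expect_equal(net$binary["AAA", "CCC"], 1L)  # exactly at: inclusive
  expect_equal(net$threshold, 1e8)

  # threshold 0 marks exactly the positive cells
  n0 <- binarize(net, 0)
  expect_equal(sum(n0$binary), sum(net$weights > 0))

  expect_error(binarize(net, -1), "non-negative")

  # idempotence and monotonicity on random tables
  set.seed(7)
  for (rep in 1:5) {
    codes <- sprintf("C%02d", 1:8)
    df <- data.frame(year = 1, exporter = sample(codes, 30, TRUE),
                     importer = sample(codes, 30, TRUE),
                     value = rlnorm(30, log(1e8), 1.5))
    net <- build_network(trade_flows(df), 1)
    taus <- sort(runif(6, 0, 5e8))
    e <- vapply(taus, function(t) sum(binarize(net, t)$binary), numeric(1))
    expect_true(all(diff(e) <= 0))
    b1 <- binarize(net, 1e8)
    b2 <- binarize(b1, 1e8)
    expect_identical(b1$binary, b2$binary)
  }
})

test_that("graph export round-trips across all three formats", {
  fl <- flows_from_edges(data.frame(
    exporter = c("AAA", "BBB", "CCC"), importer = c("BBB", "CCC", "AAA"),
    value = c(2e8, 3e8, 1.5e8)))
  net <- binarize(build_network(fl, 2019), 1e8)
  for (fmt in c("gexf", "graphml", "edgelist")) {
    path <- tempfile(fileext = paste0(".", fmt))
    export_graph(net, fmt, path)
    back <- import_graph(path, fmt)
    expect_setequal(back$nodes, net$nodes)
    want <- supplynet:::.net_edges(net)
    got <- back$edges[order(back$edges$source, back$edges$target), ]
    expect_equal(got$source, want$source)
    expect_equal(got$target, want$target)
    expect_equal(got$weight, want$weight)
  }
  expect_error(export_graph(net, "dot", tempfile()), "arg")
})

test_that("empty network exports a valid zero-edge file", {
  fl <- flows_from_edges(data.frame(exporter = "AAA", importer = "BBB",
                                    value = 5e7))
  net <- binarize(build_network(fl, 2019), 1e8)  # no edge survives
  for (fmt in c("gexf", "graphml", "edgelist")) {
    path <- tempfile(fileext = paste0(".", fmt))
    export_graph(net, fmt, path)
    back <- import_graph(path, fmt)
    expect_equal(nrow(back$edges), 0L)
  }
})
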
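mini_dict <- function() {
  parse_dictionary(parse_cif(paste(
    "data_cell_length_a",
    "_name '_cell_length_a'",
    "_category cell",
    "_type numb",
    "_units angstroms",
    "_type_conditions su",
    "_enumeration_range '0:'",
    "_list no",
    "_definition 'Cell edge a.'",
    "data_colour",
    "_name '_colour'",
    "_type char",
    "loop_ _enumeration red green blue",
    "data_frac",
    "_name '_frac'",
    "_type numb",
    "_enumeration_range '0:1'",
    "_list yes",
    "data_weight",
    "_name '_weight'",
    "_type numb",
    sep = "\n")))
}

test_that("dictionary parsing captures type, units, enum and range", {
  d <- mini_dict()
  def <- d$definitions[["_cell_length_a"]]
  expect_equal(def$type_code, "numb")
  expect_equal(def$units, "angstroms")
  expect_equal(def$range, c(min = 0, max = NA_real_))
  expect_equal(def$list_context, "forbidden-in-loop")
  expect_true(def$su_allowed)
  expect_equal(d$definitions[["_colour"]]$enumeration,
               c("red", "green", "blue"))
  expect_equal(d$definitions[["_weight"]]$list_context, "either")
})

test_that("ill-formed dictionaries are rejected", {
  expect_error(parse_dictionary(parse_cif(
    "data_a\n_name '_x'\ndata_b\n_name '_x'")), "defined twice")
  expect_error(parse_dictionary(parse_cif(
    "data_a\n_type numb")), "no _name")
  expect_error(parse_dictionary(parse_cif(
    "data_a\n_name '_x'\n_type numb\n_enumeration_range '0:1'\nloop_ _enumeration p q")),
    "mutually exclusive")
  expect_error(parse_dictionary(parse_cif(
    "data_a\n_name '_x'\n_type char\n_enumeration_range '0:1'")),
    "requires _type numb")
})

test_that("the bootstrap dictionary defines itself with zero violations", {
  doc <- parse_cif(system.file("extdata", "ddl_bootstrap.dic",
                               package = "cifsem"), file = TRUE)
  ddl <- parse_dictionary(doc)
  expect_length(validate_document(doc, ddl, strict_unknown = TRUE), 0L)
})

test_that("the core dictionary is well-formed under the bootstrap DDL", {
  doc <- parse_cif(system.file("extdata", "cifsem_core.dic",
                               package = "cifsem"), file = TRUE)
  ddl <- load_dictionary("ddl")
  expect_length(validate_document(doc, ddl, strict_unknown = TRUE), 0L)
  core <- parse_dictionary(doc)
  expect_gt(length(core$definitions), 40L)
})

test_that("validation reports each class of violation exactly once", {
  d <- mini_dict()
  codes <- function(block, ...) vapply(validate_block(block, d, ...),
                                       `[[`, "", "code")

  blk <- parse_cif("data_t\n_fictional_tag 1")$blocks[[1]]
  expect_length(codes(blk), 0L)                       # lenient by default
  expect_equal(codes(blk, strict_unknown = TRUE), "unknown-tag")

  blk <- parse_cif("data_t\n_cell_length_a abc")$blocks[[1]]
  expect_equal(codes(blk), "type-mismatch")

  blk <- parse_cif("data_t\n_colour mauve")$blocks[[1]]
  expect_equal(codes(blk), "enum-violation")
  blk <- parse_cif("data_t\n_colour red")$blocks[[1]]
  expect_length(codes(blk), 0L)
  blk <- parse_cif("data_t\n_colour ?\n_cell_length_a .")$blocks[[1]]
  expect_length(codes(blk), 0L)       # ? and . always pass value checks

  # range is closed: bounds themselves are legal
  blk <- parse_cif("data_t\nloop_\n_frac\n0\n1\n0.5")$blocks[[1]]
  expect_length(codes(blk), 0L)
  blk <- parse_cif("data_t\nloop_\n_frac\n1.01")$blocks[[1]]
  expect_equal(codes(blk), "range-violation")
  blk <- parse_cif("data_t\n_cell_length_a -1")$blocks[[1]]
  expect_equal(codes(blk), "range-violation")

  blk <- parse_cif("data_t\n_frac 0.5")$blocks[[1]]
  expect_equal(codes(blk), "loop-context")            # required in a loop
  blk <- parse_cif("data_t\nloop_\n_cell_length_a\n5")$blocks[[1]]
  expect_equal(codes(blk), "loop-context")            # forbidden in a loop

  blk <- parse_cif("data_t\n_weight 12.0(3)")$blocks[[1]]
  expect_equal(codes(blk), "missing-su-disallowed")
  blk <- parse_cif("data_t\n_cell_length_a 12.0(3)")$blocks[[1]]
  expect_length(codes(blk), 0L)
})

test_that("validation is idempotent and order-stable", {
  d <- mini_dict()
  blk <- parse_cif(
    "data_t\n_cell_length_a abc\n_colour mauve\nloop_\n_frac\n2\n3")$blocks[[1]]
  v1 <- validate_block(blk, d)
  v2 <- validate_block(blk, d)
  expect_identical(vapply(v1, `[[`, "", "code"),
                   c("type-mismatch", "enum-violation",
                     "range-violation", "range-violation"))
  expect_identical(vapply(v1, `[[`, "", "tag"), vapply(v2, `[[`, "", "tag"))
  expect_identical(vapply(v1, `[[`, "", "message"),
                   vapply(v2, `[[`, "", "message"))
})
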
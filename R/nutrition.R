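NUTRIENT_COMPONENTS <- c("calories", "carbohydrate", "protein", "sugar", "fat")

DB_COLUMNS <- c("food_id", "density_g_per_cm3", "kcal_per_g", "carb_g_per_g",
                "protein_g_per_g", "sugar_g_per_g", "fat_g_per_g")

#' Load a food density and nutrient table
#'
#' CSV with header `food_id,density_g_per_cm3,kcal_per_g,carb_g_per_g,
#' protein_g_per_g,sugar_g_per_g,fat_g_per_g`: one row per food, density in
#' g/cm^3 and nutrients per gram of food (calories in kcal/g, the rest as
#' mass fractions). Any user-provided table in this format works; the
#' package ships a small synthetic fixture with plausible values
#' (`system.file("extdata", "density_db_synthetic.csv", package =
#' "mealvol")`), not a proprietary database extract.
#'
#' @param path CSV path.
#' @return A data.frame of validated food records keyed by `food_id`.
#' @export
load_density_db <- function(path) {
  if (!file.exists(path)) stop("density table not found: ", path)
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  unknown <- setdiff(names(db), DB_COLUMNS)
  if (length(unknown) > 0L) {
    stop("unknown column in density table: ", paste(unknown, collapse = ", "))
  }
  missing_cols <- setdiff(DB_COLUMNS, names(db))
  if (length(missing_cols) > 0L) {
    stop("density table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(db$food_id)) {
    stop("duplicate food id at row ",
         which(duplicated(db$food_id))[1], ": ",
         db$food_id[duplicated(db$food_id)][1])
  }
  num <- DB_COLUMNS[-1]
  for (col in num) {
    if (!is.numeric(db[[col]])) stop("non-numeric values in column ", col)
  }
  bad <- which(db$density_g_per_cm3 <= 0)
  if (length(bad) > 0L) {
    stop("non-positive density at row ", bad[1], " (", db$food_id[bad[1]], ")")
  }
  for (col in num[-1]) {
    bad <- which(db[[col]] < 0)
    if (length(bad) > 0L) {
      stop("negative ", col, " at row ", bad[1])
    }
  }
  frac <- c("carb_g_per_g", "protein_g_per_g", "sugar_g_per_g", "fat_g_per_g")
  for (col in frac) {
    bad <- which(db[[col]] > 1)
    if (length(bad) > 0L) {
      stop(col, " exceeds 1 g/g at row ", bad[1],
           " (per-gram mass fraction expected)")
    }
  }
  db
}

per_gram_nutrients <- function(rec) {
  c(calories = rec$kcal_per_g, carbohydrate = rec$carb_g_per_g,
    protein = rec$protein_g_per_g, sugar = rec$sugar_g_per_g,
    fat = rec$fat_g_per_g)
}

#' Convert volume to weight
#'
#' `W = V * D`: measured leftover volume (cm^3) times the food's density
#' factor (g/cm^3) gives the leftover weight in grams.
#'
#' @param V volume in cm^3 (>= 0).
#' @param D density in g/cm^3 (> 0).
#' @return Weight in grams.
#' @export
volume_to_weight <- function(V, D) {
  if (any(V < 0)) stop("volume must be >= 0")
  if (any(D <= 0)) stop("density must be > 0")
  V * D
}

#' Convert weight to nutrients
#'
#' `CN(i) = W * ND_g(i)` per dietary component i: leftover weight times the
#' per-gram nutrient content.
#'
#' @param W weight in grams (>= 0).
#' @param rec one row of a [load_density_db()] table.
#' @return Named numeric vector over components calories (kcal),
#'   carbohydrate, protein, sugar, fat (g).
#' @export
weight_to_nutrients <- function(W, rec) {
  if (W < 0) stop("weight must be >= 0")
  W * per_gram_nutrients(rec)
}

#' Consumed nutrients from reported and leftover amounts
#'
#' `CoN = RN - CN` per component: what the kitchen served minus what is
#' left on the plate. A component where the calculated leftover exceeds the
#' reported serving yields a negative consumed value, retained but flagged.
#'
#' @param RN named numeric, reported (served) nutrients per component.
#' @param CN named numeric, calculated leftover nutrients, same components.
#' @return A `meal_account` list: `RN`, `CN`, `CoN`, and
#'   `leftover_exceeds_served` (logical per component).
#' @export
consumed <- function(RN, CN) {
  if (!setequal(names(RN), names(CN)) || is.null(names(RN))) {
    stop("component mismatch between RN and CN: ",
         paste(symdiff_names(RN, CN), collapse = ", "))
  }
  CN <- CN[names(RN)]
  CoN <- RN - CN
  structure(list(RN = RN, CN = CN, CoN = CoN,
                 leftover_exceeds_served = CN > RN),
            class = "meal_account")
}

symdiff_names <- function(a, b) {
  union(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
}

#' @export
print.meal_account <- function(x, ...) {
  cat("meal account (grams; calories in kcal):\n")
  df <- data.frame(component = names(x$RN),
                   served = round(x$RN),
                   leftover = round(x$CN),
                   consumed = round(x$CoN),
                   flag = ifelse(x$leftover_exceeds_served,
                                 "leftover > served", ""))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Full meal account from item volumes
#'
#' Chains volume-to-weight, weight-to-nutrients and the reported-minus-
#' leftover subtraction: per-item leftover nutrients are summed across the
#' meal per component before subtracting from the kitchen record. With no
#' leftover items the whole reported meal counts as consumed.
#'
#' @param items data.frame with columns `volume_cm3` and `food_id`
#'   (leftover volume per scanned item), or an empty data.frame.
#' @param db a [load_density_db()] table.
#' @param kitchen named numeric of reported nutrients per component (the
#'   kitchen-served amounts, grams; calories in kcal).
#' @return A `meal_account` (see [consumed()]).
#' @export
meal_report <- function(items, db, kitchen) {
  CN <- stats::setNames(numeric(length(kitchen)), names(kitchen))
  if (!is.null(items) && nrow(items) > 0L) {
    for (r in seq_len(nrow(items))) {
      rec <- db[db$food_id == items$food_id[r], , drop = FALSE]
      if (nrow(rec) == 0L) {
        stop("unknown food id: ", items$food_id[r])
      }
      W <- volume_to_weight(items$volume_cm3[r], rec$density_g_per_cm3)
      cn_item <- weight_to_nutrients(W, rec)
      CN <- CN + cn_item[names(CN)]
    }
  }
  consumed(kitchen, CN)
}

#' Read a kitchen meal record
#'
#' CSV with header `component,grams_served`, one row per dietary component
#' (calories, carbohydrate, protein, sugar, fat).
#'
#' @param path CSV path.
#' @return Named numeric vector of served amounts.
#' @export
read_kitchen_record <- function(path) {
  if (!file.exists(path)) stop("kitchen record not found: ", path)
  kr <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("component", "grams_served") %in% names(kr))) {
    stop("kitchen record needs columns component,grams_served")
  }
  unknown <- setdiff(kr$component, NUTRIENT_COMPONENTS)
  if (length(unknown) > 0L) {
    stop("unknown component(s): ", paste(unknown, collapse = ", "))
  }
  stats::setNames(as.numeric(kr$grams_served), kr$component)
}
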
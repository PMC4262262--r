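#' Default woody species parameter table
#'
#' Life-history, allometry, dispersal, seed and browsing parameters for the
#' five woody species of the model: silver birch, common broom, European
#' beech, Norway spruce and pedunculate oak. Growth rates stem from fits of
#' the Bertalanffy height curve to regional yield-table heights, crown and
#' twig-biomass allometries from measurements on solitary individuals, and
#' seed parameters from established forest succession models.
#'
#' Columns:
#' \describe{
#'   \item{name}{species label}
#'   \item{G_mean, G_sd}{annual height growth rate: mean and s.d. of the
#'     yearly draw (1/a)}
#'   \item{H_max, H_ini}{maximal and initial (seedling) height (m)}
#'   \item{A_max, A_mat}{maximal age and age at maturity (a)}
#'   \item{A_cd_const, A_cd_coeff}{crown-diameter allometry D = const * H^coeff}
#'   \item{A_biom_const, A_biom_coeff}{twig-biomass allometry
#'     B = const * L^coeff (kg dry weight for branch length L in m);
#'     \code{NA} for broom, which is never browsed}
#'   \item{ED, MD}{effective and maximum seeding distance (m)}
#'   \item{p_ED}{proportion of seeds dispersed within ED}
#'   \item{Seed_max}{maximum annual seed production per mature individual}
#'   \item{P_loss}{proportion of incoming seeds lost to unspecific predators}
#'   \item{Germ}{annual germination rate of the seed bank (the birch value is
#'     stored already halved to compensate for the missing density-dependent
#'     seedling mortality of its source model)}
#'   \item{lambda}{exponential seed-bank decay constant (1/a)}
#'   \item{Brow_mort}{annual probability that a browsed individual
#'     (height <= 1.7 m) dies at the end of the year; \code{NA} = not browsed}
#'   \item{I50}{grass cover (m2) at which a single grass species causes 50\%
#'     inhibition of seed-bank input}
#'   \item{S}{slope of the inhibition sigmoid (negative)}
#'   \item{zoochory_gated}{seeds beyond ED are delivered by jays/mammals and
#'     only land in cells that already hold at least one bush or tree and are
#'     not forest}
#'   \item{is_broom}{guild flag: bush (broom) vs tree}
#'   \item{browse_rank}{red-deer preference rank (1 = most preferred);
#'     \code{NA} = unbrowsed}
#' }
#'
#' @return A data.frame with one row per species.
#' @export
woody_species_defaults <- function() {
  df <- data.frame(
    name         = c("birch", "broom", "beech", "spruce", "oak"),
    G_mean       = c(0.03, 0.3, 0.024, 0.021, 0.028),
    G_sd         = c(0.007, 0.04, 0.002, 0.002, 0.004),
    H_max        = c(30, 3.7, 45, 45, 35),
    H_ini        = c(0.05, 0.05, 0.05, 0.05, 0.05),
    A_max        = c(100, 12, 350, 500, 800),
    A_mat        = c(15, 4, 50, 45, 50),
    A_cd_const   = c(1.146, 0.945, 0.716, 0.880, 1.144),
    A_cd_coeff   = c(0.791, 1.236, 1.073, 0.877, 0.929),
    A_biom_const = c(0.0044, NA, 0.0250, 0.1292, 0.8172),
    A_biom_coeff = c(1.247, NA, 2.180, 2.569, 3.746),
    ED           = c(200, 10, 30, 70, 30),
    MD           = c(700, 500, 200, 250, 200),
    p_ED         = c(0.95, 0.97, 0.99, 0.95, 0.99),
    Seed_max     = c(11775000, 10000, 29000, 96500, 27500),
    P_loss       = c(0.8, 0.8, 0.8, 0.8, 0.8),
    Germ         = c(0.1, 0.8, 0.7, 0.75, 0.75),
    lambda       = c(0.36, 0.063, 0.6, 0.46, 0.81),
    Brow_mort    = c(0.1, NA, 0.2, 0.1, 0.2),
    I50          = c(29.0, 26.1, 29.5, 29.3, 29.8),
    S            = c(-10, -10, -10, -10, -10),
    zoochory_gated = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    is_broom     = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    browse_rank  = c(2, NA, 3, 4, 1),
    stringsAsFactors = FALSE
  )
  validate_woody_params(df)
  df
}

#' Validate a woody species parameter table
#'
#' Checks the structural invariants every species row must satisfy.
#' @param df data.frame as returned by [woody_species_defaults()].
#' @return `df`, invisibly, or an error describing the offending row.
#' @export
validate_woody_params <- function(df) {
  needed <- c("name", "G_mean", "G_sd", "H_max", "H_ini", "A_max", "A_mat",
              "A_cd_const", "A_cd_coeff", "ED", "MD", "p_ED", "Seed_max",
              "P_loss", "Germ", "lambda", "I50", "S",
              "zoochory_gated", "is_broom")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("woody parameter table lacks columns: ",
                         paste(miss, collapse = ", "))
  with(df, {
    stopifnot(
      all(H_ini > 0), all(H_ini < H_max),
      all(A_mat > 0), all(A_mat < A_max),
      all(P_loss >= 0 & P_loss <= 1),
      all(Germ >= 0 & Germ <= 1),
      all(ED > 0), all(ED <= MD),
      all(p_ED > 0 & p_ED <= 1),
      all(lambda >= 0),
      all(I50 > 0),
      all(G_mean > 0), all(G_sd >= 0)
    )
  })
  if (anyDuplicated(df$name)) stop("duplicate species names")
  invisible(df)
}

#' Default herb-layer species parameter table
#'
#' The herbaceous layer is a deliberately minimal, cover-based stand-in for a
#' full grassland community model. It carries one aggregate tall-grass sward
#' species plus three managed-grassland grasses, a tufted-plant group, and
#' the two vegetatively spreading thorny shrubs bramble and blackthorn.
#' Bramble/blackthorn utilization values and growth parameters are the
#' published shrub characteristics; the grass rows are package defaults
#' chosen so that a sward closes within a few years while thorny shrubs need
#' decades to replace it (see the methods vignette).
#'
#' Columns: `name`; utilization indicator values `U_C`, `U_G`, `U_T`
#' (1 = intolerant .. 9 = tolerant of cutting/grazing/trampling); maximum
#' growth rate `g_max`; self-regulation factor `F_S`; `is_grass` (enters the
#' grass-inhibition sum); `is_thorny_shrub` (bramble/blackthorn: nurse
#' protection, broom space competition, competitively superior to grasses).
#'
#' @return A data.frame with one row per herb-layer species.
#' @export
herb_species_defaults <- function() {
  df <- data.frame(
    name  = c("tall_grass", "fescue", "ryegrass", "dogstail",
              "tufted_plants", "bramble", "blackthorn"),
    U_C   = c(4, 7, 8, 7, 5, 2, 3),
    U_G   = c(3, 7, 8, 7, 5, 3, 5),
    U_T   = c(4, 6, 8, 7, 5, 3, 9),
    g_max = c(18, 15, 15, 15, 10, 4.7, 4.7),
    F_S   = c(1500, 1500, 1500, 1500, 2000, 15000, 15000),
    is_grass        = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    is_thorny_shrub = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  validate_herb_params(df)
  df
}

#' Validate a herb species parameter table
#' @param df data.frame as returned by [herb_species_defaults()].
#' @return `df`, invisibly.
#' @export
validate_herb_params <- function(df) {
  needed <- c("name", "U_C", "U_G", "U_T", "g_max", "F_S",
              "is_grass", "is_thorny_shrub")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("herb parameter table lacks columns: ",
                         paste(miss, collapse = ", "))
  u <- as.matrix(df[, c("U_C", "U_G", "U_T")])
  stopifnot(all(u >= 1 & u <= 9), all(df$g_max > 0), all(df$F_S > 0))
  if (anyDuplicated(df$name)) stop("duplicate species names")
  invisible(df)
}

#' Red-deer browser parameters
#'
#' Demand-side constants of the browsing budget: daily dry-weight intake per
#' 100 kg of deer in summer and winter, season lengths, the woody fraction of
#' the diet, the reference herd used to define a "standard deer", and the
#' geometry of browsing (bite length, height limits).
#'
#' @param density deer per 100 ha (spatially uniform, constant in time).
#' @param dsd,sdays,dwd,wdays,frw demand constants: daily summer/winter
#'   demand (kg dw per 100 kg deer), summer/winter days, woody diet fraction.
#' @param herd data.frame with columns `count` and `mass_kg`; the default is
#'   the reference herd of 5 adult males (105 kg), 10 adult females (70 kg)
#'   and 20 juveniles (42.5 kg).
#' @param bite_length branch length eaten per browsing event (m).
#' @param max_forage_height trees taller than this provide no forage (m).
#' @param max_browse_height leader shoots up to this height are reachable, so
#'   only individuals at or below it stop growing or die from browsing (m).
#' @param instant_death_height browsed individuals below this height die
#'   immediately (m).
#' @param nurse_P50,nurse_R50 blackthorn / bramble cover (m2) giving
#'   half-protection in the nurse factor; blackthorn protects more strongly.
#' @param nurse_slope Hill slope of the nurse sigmoid.
#' @return A list of class `browser_params`.
#' @export
browser_params <- function(density = 22,
                           dsd = 2.5, sdays = 214, dwd = 3.0, wdays = 152,
                           frw = 0.268,
                           herd = data.frame(count = c(5, 10, 20),
                                             mass_kg = c(105, 70, 42.5)),
                           bite_length = 0.1,
                           max_forage_height = 5,
                           max_browse_height = 1.7,
                           instant_death_height = 0.2,
                           nurse_P50 = 25, nurse_R50 = 50,
                           nurse_slope = 4) {
  stopifnot(density >= 0, dsd > 0, sdays > 0, dwd > 0, wdays > 0,
            frw >= 0, frw <= 1, nrow(herd) >= 1,
            all(herd$count > 0), all(herd$mass_kg >= 0),
            bite_length > 0, instant_death_height < max_browse_height,
            max_browse_height <= max_forage_height)
  structure(list(density = density, dsd = dsd, sdays = sdays, dwd = dwd,
                 wdays = wdays, frw = frw, herd = herd,
                 bite_length = bite_length,
                 max_forage_height = max_forage_height,
                 max_browse_height = max_browse_height,
                 instant_death_height = instant_death_height,
                 nurse_P50 = nurse_P50, nurse_R50 = nurse_R50,
                 nurse_slope = nurse_slope),
            class = "browser_params")
}

#' Mean mass of a "standard deer"
#'
#' The demand budget is scaled by the mean body mass of an individual in the
#' reference herd.
#' @param herd data.frame with columns `count` and `mass_kg`.
#' @return Mean individual mass (kg).
#' @export
standard_deer_weight <- function(herd) {
  if (is.null(herd) || nrow(herd) == 0) stop("empty herd")
  sum(herd$count * herd$mass_kg) / sum(herd$count)
}

#' Annual woody-browse demand per standard deer
#'
#' D = (dsd * sdays + dwd * wdays) * (sdeer / 100) * frw, in kg dry weight
#' per year, where sdeer is the standard-deer mass.
#' @param params a [browser_params()] object.
#' @return Demand (kg dw / a) of one standard deer.
#' @export
annual_demand_per_deer <- function(params) {
  sdeer <- standard_deer_weight(params$herd)
  (params$dsd * params$sdays + params$dwd * params$wdays) *
    (sdeer / 100) * params$frw
}

#' Read a woody species parameter table from CSV
#' @param path CSV file with the columns of [woody_species_defaults()].
#' @return Validated data.frame.
#' @export
read_woody_params <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("zoochory_gated", "is_broom"))
    df[[col]] <- as.logical(df[[col]])
  validate_woody_params(df)
  df
}

#' Read a herb species parameter table from CSV
#' @param path CSV file with the columns of [herb_species_defaults()].
#' @return Validated data.frame.
#' @export
read_herb_params <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("is_grass", "is_thorny_shrub"))
    df[[col]] <- as.logical(df[[col]])
  validate_herb_params(df)
  df
}
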
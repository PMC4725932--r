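#' @include AllClasses.R
NULL

#' Number of individuals in a cohort
#' @param x an [AphidCohort-class].
#' @return integer.
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname nIndividuals
#' @export
setMethod("nIndividuals", "AphidCohort", function(x) length(x@ids))

#' Host-plant label of a cohort or parameter set
#' @param x an [AphidCohort-class] or [PopulationParameters-class].
#' @return character scalar.
#' @export
setGeneric("hostLabel", function(x) standardGeneric("hostLabel"))

#' @rdname hostLabel
#' @export
setMethod("hostLabel", "AphidCohort", function(x) x@host)

#' @rdname hostLabel
#' @export
setMethod("hostLabel", "PopulationParameters", function(x) x@host)

#' Age-specific survival schedule l_x
#' @param x a [DemographySchedules-class].
#' @return numeric vector over ages 0..maxAge.
#' @export
setGeneric("survivalSchedule", function(x) standardGeneric("survivalSchedule"))

#' @rdname survivalSchedule
#' @export
setMethod("survivalSchedule", "DemographySchedules", function(x) x@lx)

#' Age-specific fecundity schedule m_x
#' @param x a [DemographySchedules-class].
#' @return numeric vector over ages 0..maxAge.
#' @export
setGeneric("fecunditySchedule",
           function(x) standardGeneric("fecunditySchedule"))

#' @rdname fecunditySchedule
#' @export
setMethod("fecunditySchedule", "DemographySchedules", function(x) x@mx)

#' Age-stage occupancy matrix s_xj
#' @param x a [DemographySchedules-class].
#' @return numeric matrix, ages x stages.
#' @export
setGeneric("stageOccupancy", function(x) standardGeneric("stageOccupancy"))

#' @rdname stageOccupancy
#' @export
setMethod("stageOccupancy", "DemographySchedules", function(x) x@sxj)

#' Point estimates of population parameters
#' @param x a [PopulationParameters-class].
#' @return named numeric vector.
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' @rdname estimates
#' @export
setMethod("estimates", "PopulationParameters", function(x) x@estimates)

#' Bootstrap standard errors of population parameters
#' @param x a [PopulationParameters-class].
#' @return named numeric vector.
#' @export
setGeneric("standardErrors", function(x) standardGeneric("standardErrors"))

#' @rdname standardErrors
#' @export
setMethod("standardErrors", "PopulationParameters", function(x) x@se)

#' Recording duration of an EPG experiment
#' @param x an [EPGExperiment-class].
#' @return numeric, seconds.
#' @export
setGeneric("recordingDuration",
           function(x) standardGeneric("recordingDuration"))

#' @rdname recordingDuration
#' @export
setMethod("recordingDuration", "EPGExperiment", function(x) x@duration)

#' Waveform intervals of an EPG experiment
#' @param x an [EPGExperiment-class].
#' @return data.frame of intervals.
#' @export
setGeneric("waveformIntervals",
           function(x) standardGeneric("waveformIntervals"))

#' @rdname waveformIntervals
#' @export
setMethod("waveformIntervals", "EPGExperiment", function(x) x@intervals)
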
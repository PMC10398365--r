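category,word
morning,morning
morning,mornings
morning,sunrise
morning,dawn
morning,daybreak
afternoon,afternoon
afternoon,afternoons
afternoon,midday
afternoon,noon
evening,evening
evening,evenings
evening,dusk
evening,sunset
evening,sundown
night,night
night,nights
night,midnight
night,overnight
night,nighttime
today,today
today,tonight
yesterday,yesterday
tomorrow,tomorrow
day,day
day,days
day,daily
week,week
week,weeks
week,weekly
week,weekend
week,weekday
month,month
month,months
month,monthly
year,year
year,years
year,yearly
year,annual
year,anniversary
hour,hour
hour,hours
hour,hourly
minute,minute
minute,minutes
moment,moment
moment,moments
moment,instant
moment,seconds
season,season
season,seasons
season,winter
season,spring
season,summer
season,autumn
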
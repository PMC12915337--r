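# PM10 AQI breakpoints (US EPA convention): contiguous AQI ranges mapped
# piecewise-linearly to 24-h PM10 mass concentration in ug/m3. Editable:
# swap in any contiguous, non-overlapping table with the same fields.
pollutant: pm10
units: "ug/m3"
breakpoints:
  - {aqi_lo: 0,   aqi_hi: 50,  conc_lo: 0,   conc_hi: 54}
  - {aqi_lo: 51,  aqi_hi: 100, conc_lo: 55,  conc_hi: 154}
  - {aqi_lo: 101, aqi_hi: 150, conc_lo: 155, conc_hi: 254}
  - {aqi_lo: 151, aqi_hi: 200, conc_lo: 255, conc_hi: 354}
  - {aqi_lo: 201, aqi_hi: 300, conc_lo: 355, conc_hi: 424}
  - {aqi_lo: 301, aqi_hi: 400, conc_lo: 425, conc_hi: 504}
  - {aqi_lo: 401, aqi_hi: 500, conc_lo: 505, conc_hi: 604}
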
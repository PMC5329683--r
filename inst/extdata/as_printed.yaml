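# as_printed: the island model's published parameterisation, verbatim.
# Every value is the published assignment (visitor count 1e6/yr, stay-day
# fractions 0.1/0.2/0.5/0.1/0.1, 10000 residents, land 6.62 km2, inshore
# 1500 km2, temp 8 degC, rade 1.2 MJ m-2 yr-1, all ce_* coefficients).
# One documented reading: growth_r is stored as 1500 g C m-2 yr-1 (the
# published figure 1500000 is physically impossible at its stated unit;
# see the methods vignette). Initial stocks are zero as published, which
# makes all stock-proportional ecosystem fluxes identically zero.
name: as_printed
horizon:
  value: 1.0
  unit: yr
dt:
  value: 0.08333333333333333
  unit: yr
temp_mode: clamp
forcings:
  temp:
    value: 8.0
    unit: degC
  rade:
    value: 1.19999999999999996
    unit: MJ m-2 yr-1
  nv:
    value: 1000000.0
    unit: visitor yr-1
  ni:
    value: 10000.0
    unit: person
  land_area:
    value: 6.62000000000000011
    unit: km2
  inshore_area:
    value: 1500.0
    unit: km2
profile:
  sd:
    value:
    - 0.10000000000000001
    - 0.20000000000000001
    - 0.5
    - 0.10000000000000001
    - 0.10000000000000001
    unit: '1'
  hotel_r:
    value: 0.29999999999999999
    unit: '1'
  ph_r:
    value: 0.69999999999999996
    unit: '1'
  moto_r:
    value: 0.20000000000000001
    unit: '1'
  pc_r:
    value: 0.10000000000000001
    unit: '1'
  ssd_r:
    value: 0.69999999999999996
    unit: '1'
  pd_moto:
    value: 6.0
    unit: km day-1
  pd_pc:
    value: 20.0
    unit: km day-1
  pd_ssd:
    value: 14.0
    unit: km day-1
params:
  w_growth_r:
    value: 0.10000000000000001
    unit: stock-1 yr-1
  f_growth_r:
    value: 0.10000000000000001
    unit: stock-1 yr-1
  w_re_r:
    value: 0.20000000000000001
    unit: stock-1 yr-1 degC-1
  f_re_r:
    value: 0.20000000000000001
    unit: stock-1 yr-1 degC-1
  dec_r:
    value: 0.14999999999999999
    unit: stock-1 yr-1 degC-1
  ads_r:
    value: 0.10000000000000001
    unit: stock-1 yr-1 degC-1
  forest_frac:
    value: 0.53000000000000003
    unit: '1'
  tidal_frac:
    value: 0.14000000000000001
    unit: '1'
  aqu_frac:
    value: 0.005
    unit: '1'
  growth_r:
    value: 1500.0
    unit: g C m-2 yr-1
  shell_c_r:
    value: 0.94999999999999996
    unit: '1'
  ce_aqu:
    value: 50000.0
    unit: g CO2 km-2 yr-1
  ce_car:
    value: 5400000.0
    unit: g CO2 car-1 yr-1
  ce_desalination:
    value: 2784.0
    unit: g CO2 t-1
  ce_ferry:
    value: 106.0
    unit: g CO2 km-1
  ce_fishing:
    value: 1670.0
    unit: g CO2 day-1
  ce_hotel:
    value: 7900.0
    unit: g CO2 night-1
  ce_moto:
    value: 0.0
    unit: g CO2 km-1
  ce_pc:
    value: 63.0
    unit: g CO2 km-1
  ce_ph:
    value: 1619.0
    unit: g CO2 night-1
  ce_shopping:
    value: 344.0
    unit: g CO2 day-1
  ce_ssb:
    value: 40.0
    unit: g CO2 km-1
  ce_visiting:
    value: 417.0
    unit: g CO2 day-1
  ce_wa:
    value: 15300.0
    unit: g CO2 day-1
  dis_ferry:
    value: 140.0
    unit: km
  per_wc:
    value: 1.19999999999999996
    unit: t person-1 day-1
  per_waste:
    value: 1.10000000000000009
    unit: kg person-1 day-1
  pch4_waste:
    value: 80000.0
    unit: g CH4 kg-1
  ch4_use_r:
    value: 1.0
    unit: '1'
  car_r:
    value: 0.10000000000000001
    unit: '1'
  food_import:
    value: 0.0
    unit: tC yr-1
  residential_electricity:
    value: 0.0
    unit: tC yr-1
init:
  co2_exchange: 0.0
  forest_c: 0.0
  wetland_c: 0.0
  shell_c: 0.0
  soil_c: 0.0
  waste_ch4: 0.0
  total_ch4: 0.0
flux_scale: []
extra_sinks: []

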
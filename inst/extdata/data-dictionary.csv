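table,column,type,units,description
pixels,pixel_id,integer,,unique pixel identifier
pixels,row,integer,pixels,grid row of the 1-km pixel
pixels,col,integer,pixels,grid column of the 1-km pixel
pixels,elev,numeric,m,elevation
pixels,aet,numeric,mm,actual evapotranspiration (climate normal)
pixels,deficit,numeric,mm,climatic water deficit (PET minus AET)
pixels,soil_awc,numeric,volumetric fraction,soil available water capacity
pixels,soil_bd,numeric,kg/m^3,soil bulk density
pixels,wtd,numeric,m,water-table depth
pixels,cti,numeric,unitless,compound topographic index (mean of 30-m subgrid)
pixels,hli,numeric,unitless,heat-load index (1-km mean)
pixels,biome,character,,forest or shrub-steppe
pixels,ecosystem,character,,ecosystem type code within biome
pixels,shade_dens,numeric,percent,percent of 30-m subcells with HLI <= 0.6
pixels,landcover,character,,majority 30-m landcover code
truth,pixel_id,integer,,pixel identifier
truth,baseline_evi_true,numeric,EVI,true baseline summer EVI strictly between 0 and 1
truth,s_mod_true,numeric,fraction,true fractional EVI reduction under moderate drought
truth,s_sev_true,numeric,fraction,true fractional EVI reduction under severe drought
truth,true_timescale,integer,months,SPEI timescale the pixel truly responds to
truth,disturbed_flag,logical,,pixel receives an abrupt permanent EVI drop
truth,trend_flag,logical,,pixel receives an additive linear EVI drift
truth,trend_slope,numeric,EVI/year,slope of the injected trend
climate,pixel_id,integer,,pixel identifier
climate,year,integer,calendar year,
climate,month,integer,1-12,calendar month
climate,prcp,numeric,mm,monthly precipitation
climate,pet,numeric,mm,monthly potential evapotranspiration
spei,pixel_id,integer,,pixel identifier
spei,year,integer,calendar year,anchored at the configured end month
spei,timescale,integer,months,aggregation window
spei,spei,numeric,standardized,standardized precipitation-evapotranspiration index
spei,drought_class,character,,pluvial / baseline / moderate / severe
evi,pixel_id,integer,,pixel identifier
evi,year,integer,calendar year,
evi,evi_summer,numeric,EVI,mean June-August EVI
sensitivity,pixel_id,integer,,pixel identifier
sensitivity,s_mod_<k>,numeric,percent,moderate-drought S' at timescale k
sensitivity,s_sev_<k>,numeric,percent,severe-drought S' at timescale k
sensitivity,baseline_<k>,numeric,EVI,baseline EVI at timescale k
sensitivity,n_base_<k>,integer,years,baseline-class year count at timescale k
sensitivity,n_mod_<k>,integer,years,moderate-class year count at timescale k
sensitivity,n_sev_<k>,integer,years,severe-class year count at timescale k
sensitivity,s_mod_max,numeric,percent,maximum moderate-drought S' across timescales
sensitivity,s_sev_max,numeric,percent,maximum severe-drought S' across timescales
sensitivity,timescale_mod,integer,months,timescale attaining s_mod_max
sensitivity,timescale_sev,integer,months,timescale attaining s_sev_max
sensitivity,valid_mod,logical,,moderate sensitivity passed validity rules
sensitivity,valid_sev,logical,,severe sensitivity passed validity rules
model_table,drought_exp,numeric,percent,cumulative drought exposure 1990-2016
exclusion_ledger,rule,character,,disturbed / trending / landcover / retained / total
exclusion_ledger,n,integer,pixels,count attributed to the rule
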
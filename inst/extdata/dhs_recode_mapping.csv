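package_column,dhs_variable,recode_rule
outcome,h11,"2 ('yes, last two weeks') -> 1; 0 ('no') -> 0; 8/9 (don't know/missing) -> NA"
group,v106,"0 (no education) -> illiterate; 1/2/3 (primary/secondary/higher) -> literate via recode_education()"
weight,v005,"v005 / 1e6 (standard DHS woman's weight rescaling)"
cluster_id,v001,"cluster number, prefixed with the country code to keep ids unique across surveys"
country_id,v000,"country code of the recode file"
child_age,b19,"b19 < 12 -> infant; otherwise -> 12-59 months (hw1 where b19 absent)"
child_sex,b4,"1 -> male; 2 -> female"
household_head,v151,"1 -> male; 2 -> female"
maternal_age,v013,"1-2 -> 15-24; 3-4 -> 25-34; 5-7 -> 35-49"
wealth,v190,"1 -> poorest; 2 -> poorer; 3 -> middle; 4 -> richer; 5 -> richest"
employment,v714,"1 -> employed; 0 -> unemployed"
media_access,v157 v158 v159,"any of newspaper/radio/tv at least once a week (value >= 1) -> yes; else no"
water_source,v113,"10-31,41,51,61-73 improved codes -> improved; else unimproved (WHO/UNICEF JMP ladder)"
toilet,v116,"10-22,41 improved codes -> improved; else unimproved (JMP ladder)"
marital_status,v501,"0 -> never married; 1/2 -> currently married; 3/4/5 -> formerly married"
cooking_fuel,v161,"1-4 (electricity/LPG/natural gas/biogas) -> clean; else unclean"
housing,v127 v128 v129,"finished floor, wall and roof materials (codes 30+) -> improved; else unimproved"
birth_weight,m18,"1/2 (very large/larger than average) and 3 (average) -> average+; 4 -> small; 5 -> very small"
birth_interval,b11,"missing (first birth) -> first birth; < 36 -> <36 months; >= 36 -> 36+ months"
birth_order,bord,"1 -> 1; 2 -> 2; 3 -> 3; >= 4 -> 4+"
residence,v025,"1 -> urban; 2 -> rural"
neighbourhood_ses,derived,"computed by compute_neighbourhood_ses() from v190 (bottom two quintiles = poor) and v714 within v001 clusters; quintile 1 = highest SES"
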
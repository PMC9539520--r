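{"beta":{"intercept":2.2,"biomass":0.8,"bodymass":0.5,"hatch":-0.3,"age":0,"age_bodymass":0.6},"scaling":{"center":{"biomass":6.75352409630615,"bodymass":0.745407808277783,"hatch":157.736842105263,"age":10},"scale":{"biomass":8.70858913558124,"bodymass":0.676093568607867,"hatch":6.56055909755522,"age":12.4096736459909}},"growth_K":0.18,"growth_Ti":12,"A0":249,"chicks":[{"chick_id":"C0001","brood_id":"B2009_01","plot":"South","year":2009,"hatch_day":156,"K_dev":0.000776920665640446,"death_age":1,"fledged":false},{"chick_id":"C0002","brood_id":"B2009_01","plot":"South","year":2009,"hatch_day":156,"K_dev":0.00889074746363087,"death_age":16,"fledged":false},{"chick_id":"C0003","brood_id":"B2009_02","plot":"North","year":2009,"hatch_day":161,"K_dev":0.0278713858471404,"death_age":2,"fledged":false},{"chick_id":"C0004","brood_id":"B2009_03","plot":"South","year":2009,"hatch_day":158,"K_dev":-0.0208494903791944,"death_age":3,"fledged":false},{"chick_id":"C0005","brood_id":"B2009_04","plot":"North","year":2009,"hatch_day":154,"K_dev":-0.011458609237887,"death_age":18,"fledged":false},{"chick_id":"C0006","brood_id":"B2009_05","plot":"South","year":2009,"hatch_day":158,"K_dev":0.0213429153538245,"death_age":1,"fledged":false},{"chick_id":"C0007","brood_id":"B2009_05","plot":"South","year":2009,"hatch_day":158,"K_dev":0.0403302483761746,"death_age":null,"fledged":true},{"chick_id":"C0008","brood_id":"B2009_06","plot":"North","year":2009,"hatch_day":155,"K_dev":0.0129234356779249,"death_age":null,"fledged":true},{"chick_id":"C0009","brood_id":"B2009_07","plot":"South","year":2009,"hatch_day":164,"K_dev":-0.0260631125116758,"death_age":14,"fledged":false},{"chick_id":"C0010","brood_id":"B2009_07","plot":"South","year":2009,"hatch_day":164,"K_dev":0.000507351928191322,"death_age":10,"fledged":false},{"chick_id":"C0011","brood_id":"B2009_08","plot":"North","year":2009,"hatch_day":157,"K_dev":-0.0101416890485159,"death_age":null,"fledged":true},{"chick_id":"C0012","brood_id":"B2010_01","plot":"South","year":2010,"hatch_day":154,"K_dev":-0.00958129859274689,"death_age":1,"fledged":false},{"chick_id":"C0013","brood_id":"B2010_02","plot":"North","year":2010,"hatch_day":160,"K_dev":-0.0135272201208876,"death_age":null,"fledged":true},{"chick_id":"C0014","brood_id":"B2010_03","plot":"South","year":2010,"hatch_day":161,"K_dev":-0.0157837768483075,"death_age":8,"fledged":false},{"chick_id":"C0015","brood_id":"B2010_04","plot":"North","year":2010,"hatch_day":156,"K_dev":0.00960779741698936,"death_age":null,"fledged":true},{"chick_id":"C0016","brood_id":"B2010_05","plot":"South","year":2010,"hatch_day":156,"K_dev":0.00654742781178096,"death_age":8,"fledged":false},{"chick_id":"C0017","brood_id":"B2010_06","plot":"North","year":2010,"hatch_day":161,"K_dev":0.0142531710532234,"death_age":7,"fledged":false},{"chick_id":"C0018","brood_id":"B2010_07","plot":"South","year":2010,"hatch_day":153,"K_dev":-0.00920729404941219,"death_age":null,"fledged":true},{"chick_id":"C0019","brood_id":"B2010_08","plot":"North","year":2010,"hatch_day":155,"K_dev":0.0112311815021092,"death_age":null,"fledged":true}],"seed":20}
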
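item_id	value_type
item01	universalism
item02	universalism
item03	universalism
item04	universalism
item05	universalism
item06	universalism
item07	universalism
item08	benevolence
item09	benevolence
item10	benevolence
item11	benevolence
item12	benevolence
item13	benevolence
item14	benevolence
item15	benevolence
item16	benevolence
item17	tradition
item18	tradition
item19	tradition
item20	tradition
item21	tradition
item22	tradition
item23	conformity
item24	conformity
item25	conformity
item26	conformity
item27	security
item28	security
item29	security
item30	security
item31	security
item32	security
item33	power
item34	power
item35	power
item36	power
item37	power
item38	achievement
item39	achievement
item40	achievement
item41	achievement
item42	achievement
item43	achievement
item44	hedonism
item45	hedonism
item46	stimulation
item47	stimulation
item48	stimulation
item49	self-direction
item50	self-direction
item51	self-direction
item52	self-direction
item53	self-direction
item54	self-direction
item55	NA
item56	NA
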
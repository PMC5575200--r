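country,locality,haplotype,count
China,Heibei/Beijing,H1,75
China,Heibei/Beijing,H2,1
China,Heibei/Beijing,H3,12
China,Heibei/Beijing,H4,1
China,Heibei/Beijing,H5,1
China,Heibei/Beijing,H6,1
China,Heibei/Beijing,H7,1
China,Heibei/Beijing,H10,1
China,Heibei/Beijing,H11,1
China,Heibei/Beijing,H12,1
China,Heibei/Beijing,H13,3
China,Heibei/Beijing,H14,1
China,Heibei/Beijing,H15,1
China,Heibei/Beijing,H16,1
China,Heibei/Beijing,H17,1
China,Heibei/Beijing,H18,1
China,Heibei/Beijing,H19,1
China,Heibei/Beijing,H20,1
China,Heibei/Beijing,H21,1
China,Xi'an,H1,1
China,Xi'an,H33,2
China,Xi'an,H45,1
China,Xi'an,H53,2
China,Nanjing,H2,5
China,Nanjing,H3,1
China,Nanjing,H22,2
China,Nanjing,H26,2
China,Nanjing,H34,1
China,Nanjing,H55,1
China,Anhui Province,H1,3
China,Anhui Province,H2,1
China,Anhui Province,H3,4
China,Anhui Province,H33,1
China,Fuzhou,H1,7
China,Haidain,H1,5
China,Haidain,H46,1
China,Hefei,H22,4
China,Hefei,H54,3
China,Kunming,H1,1
China,Kunming,H6,1
China,Kunming,H17,3
Japan,Tsukuba,H9,1
Japan,Tsukuba,H23,1
Japan,Tsukuba,H24,1
Japan,Tsukuba,H27,1
Japan,Tsukuba,H39,1
Japan,Tsukuba,H41,4
Japan,Tsukuba,H44,2
Japan,Tsukuba,H45,4
Japan,Tsukuba,H56,1
Japan,Yokote,H27,1
Japan,Yokote,H39,2
Japan,Yokote,H40,2
Japan,Yokote,H41,1
Japan,Yokote,H42,1
Japan,Yokote,H49,1
Japan,Yokote,H50,1
Japan,Yokote,H51,3
Japan,Yokote,H57,1
Japan,Yuzawa,H1,1
Japan,Yuzawa,H23,1
Japan,Yuzawa,H39,1
Japan,Yuzawa,H40,4
Japan,Yuzawa,H43,1
Japan,Yuzawa,H48,1
Japan,Yuzawa,H51,5
Japan,Yuzawa,H52,1
Republic of Korea,Yangpyeong,H22,1
Republic of Korea,Suwon,H2,1
Republic of Korea,Suwon,H22,1
Republic of Korea,Suwon,H25,1
Republic of Korea,Suwon,H38,1
Republic of Korea,Chungcheong Province,H28,1
Republic of Korea,Chungcheong Province,H35,1
Republic of Korea,Chungcheong Province,H36,1
Republic of Korea,Chungcheong Province,H37,1
Republic of Korea,East Seoul,H22,1
Republic of Korea,East Seoul,H29,1
Republic of Korea,Anyang,H22,1
United States,New Jersey,H1,14
United States,Maryland,H1,14
United States,Georgia,H1,6
United States,Delaware,H1,3
United States,Massachusetts,H1,2
United States,Mississippi,H1,2
United States,New York,H1,2
United States,Pennsylvania,H1,6
United States,Virginia,H1,6
United States,West Virginia,H1,6
United States,Ohio,H1,4
United States,Michigan,H1,5
United States,California (pre-2008),H1,11
United States,California (post-2008),H3,1
United States,California (post-2008),H7,1
United States,Oregon,H1,1
United States,Oregon,H3,10
United States,Oregon,H23,1
United States,Oregon,H47,9
United States,Washington,H3,2
United States,Washington,H47,2
Canada,Canada,H1,49
Canada,Canada,H14,1
Canada,Canada,H17,1
Switzerland,North Switzerland,H3,164
Switzerland,North Switzerland,H8,30
Switzerland,North Switzerland,H9,1
Switzerland,Lugano,H1,2
Switzerland,Lugano,H3,23
Switzerland,Lugano,H8,1
Switzerland,Ticino,H3,2
Italy,Emilia-Romagna,H1,31
Italy,Lombardy,H1,1
Italy,Lombardy,H3,7
Italy,Lombardy,H8,1
France,Schiltigheim,H1,1
France,Schiltigheim,H3,136
France,Schiltigheim,H8,2
Hungary,Budapest,H1,83
Hungary,Budapest,H3,1
Greece,Athens,H1,18
Greece,Athens,H3,4
Greece,Athens,H22,2
Greece,Athens,H30,1
Greece,Athens,H31,1
Greece,Athens,H32,8
Greece,Athens,H33,23
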
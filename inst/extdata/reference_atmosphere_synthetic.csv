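"year","d13c_air","ca","provenance"
1850,-6.4,285,"synthetic"
1851,-6.40012,285.0035,"synthetic"
1852,-6.40041786427038,285.014,"synthetic"
1853,-6.4008669608867,285.0315,"synthetic"
1854,-6.40145508790385,285.056,"synthetic"
1855,-6.40217433899103,285.0875,"synthetic"
1856,-6.40301893315309,285.126,"synthetic"
1857,-6.4039843521708,285.1715,"synthetic"
1858,-6.40506691037737,285.224,"synthetic"
1859,-6.40626350982558,285.2835,"synthetic"
1860,-6.40757148813376,285.35,"synthetic"
1861,-6.40898851772833,285.4235,"synthetic"
1862,-6.41051253582792,285.504,"synthetic"
1863,-6.41214169391038,285.5915,"synthetic"
1864,-6.41387432010662,285.686,"synthetic"
1865,-6.41570889049712,285.7875,"synthetic"
1866,-6.41764400673275,285.896,"synthetic"
1867,-6.41967837826709,286.0115,"synthetic"
1868,-6.42181080802747,286.134,"synthetic"
1869,-6.42404018070052,286.2635,"synthetic"
1870,-6.42636545303935,286.4,"synthetic"
1871,-6.42878564575768,286.5435,"synthetic"
1872,-6.43129983668638,286.694,"synthetic"
1873,-6.43390715494607,286.8515,"synthetic"
1874,-6.43660677594665,287.016,"synthetic"
1875,-6.43939791706606,287.1875,"synthetic"
1876,-6.44227983389221,287.366,"synthetic"
1877,-6.44525181693537,287.5515,"synthetic"
1878,-6.44831318873668,287.744,"synthetic"
1879,-6.45146330131233,287.9435,"synthetic"
1880,-6.45470153388411,288.15,"synthetic"
1881,-6.45802729085555,288.3635,"synthetic"
1882,-6.46144,288.584,"synthetic"
1883,-6.46493911083234,288.8115,"synthetic"
1884,-6.46852409314068,289.046,"synthetic"
1885,-6.47219443565805,289.2875,"synthetic"
1886,-6.47594964485705,289.536,"synthetic"
1887,-6.47978924385285,289.7915,"synthetic"
1888,-6.48371277140233,290.054,"synthetic"
1889,-6.48771978098831,290.3235,"synthetic"
1890,-6.49180983997984,290.6,"synthetic"
1891,-6.49598252886037,290.8835,"synthetic"
1892,-6.50023744051676,291.174,"synthetic"
1893,-6.50457417958307,291.4715,"synthetic"
1894,-6.50899236183361,291.776,"synthetic"
1895,-6.51349161362063,292.0875,"synthetic"
1896,-6.51807157135228,292.406,"synthetic"
1897,-6.52273188100736,292.7315,"synthetic"
1898,-6.52747219768323,293.064,"synthetic"
1899,-6.53229218517431,293.4035,"synthetic"
1900,-6.5371915155782,293.75,"synthetic"
1901,-6.54216986892729,294.1035,"synthetic"
1902,-6.54722693284371,294.464,"synthetic"
1903,-6.55236240221557,294.8315,"synthetic"
1904,-6.55757597889304,295.206,"synthetic"
1905,-6.56286737140249,295.5875,"synthetic"
1906,-6.56823629467741,295.976,"synthetic"
1907,-6.57368246980483,296.3715,"synthetic"
1908,-6.57920562378612,296.774,"synthetic"
1909,-6.58480548931099,297.1835,"synthetic"
1910,-6.59048180454389,297.6,"synthetic"
1911,-6.59623431292194,298.0235,"synthetic"
1912,-6.60206276296338,298.454,"synthetic"
1913,-6.60796690808617,298.8915,"synthetic"
1914,-6.61394650643566,299.336,"synthetic"
1915,-6.6200013207211,299.7875,"synthetic"
1916,-6.62613111806017,300.246,"synthetic"
1917,-6.63233566983109,300.7115,"synthetic"
1918,-6.6386147515319,301.184,"synthetic"
1919,-6.6449681426463,301.6635,"synthetic"
1920,-6.65139562651586,302.15,"synthetic"
1921,-6.65789699021804,302.6435,"synthetic"
1922,-6.66447202444976,303.144,"synthetic"
1923,-6.67112052341616,303.6515,"synthetic"
1924,-6.67784228472428,304.166,"synthetic"
1925,-6.68463710928136,304.6875,"synthetic"
1926,-6.69150480119751,305.216,"synthetic"
1927,-6.69844516769248,305.7515,"synthetic"
1928,-6.70545801900634,306.294,"synthetic"
1929,-6.71254316831386,306.8435,"synthetic"
1930,-6.71970043164232,307.4,"synthetic"
1931,-6.7269296277927,307.9635,"synthetic"
1932,-6.73423057826393,308.534,"synthetic"
1933,-6.74160310718019,309.1115,"synthetic"
1934,-6.74904704122092,309.696,"synthetic"
1935,-6.75656220955361,310.2875,"synthetic"
1936,-6.76414844376908,310.886,"synthetic"
1937,-6.77180557781921,311.4915,"synthetic"
1938,-6.7795334479569,312.104,"synthetic"
1939,-6.78733189267835,312.7235,"synthetic"
1940,-6.79520075266729,313.35,"synthetic"
1941,-6.80313987074129,313.9835,"synthetic"
1942,-6.81114909179996,314.624,"synthetic"
1943,-6.81922826277488,315.2715,"synthetic"
1944,-6.8273772325814,315.926,"synthetic"
1945,-6.83559585207193,316.5875,"synthetic"
1946,-6.84388397399094,317.256,"synthetic"
1947,-6.8522414529314,317.9315,"synthetic"
1948,-6.86066814529269,318.614,"synthetic"
1949,-6.86916390923985,319.3035,"synthetic"
1950,-6.8777286046642,320,"synthetic"
1951,-6.88636209314521,320.7035,"synthetic"
1952,-6.89506423791357,321.414,"synthetic"
1953,-6.90383490381544,322.1315,"synthetic"
1954,-6.91267395727781,322.856,"synthetic"
1955,-6.92158126627491,323.5875,"synthetic"
1956,-6.93055670029567,324.326,"synthetic"
1957,-6.9396001303122,325.0715,"synthetic"
1958,-6.94871142874911,325.824,"synthetic"
1959,-6.95789046945388,326.5835,"synthetic"
1960,-6.96713712766799,327.35,"synthetic"
1961,-6.97645127999893,328.1235,"synthetic"
1962,-6.98583280439307,328.904,"synthetic"
1963,-6.99528158010923,329.6915,"synthetic"
1964,-7.00479748769304,330.486,"synthetic"
1965,-7.01438040895202,331.2875,"synthetic"
1966,-7.02403022693137,332.096,"synthetic"
1967,-7.03374682589039,332.9115,"synthetic"
1968,-7.04353009127958,333.734,"synthetic"
1969,-7.05337990971836,334.5635,"synthetic"
1970,-7.06329616897339,335.4,"synthetic"
1971,-7.07327875793744,336.2435,"synthetic"
1972,-7.08332756660888,337.094,"synthetic"
1973,-7.09344248607164,337.9515,"synthetic"
1974,-7.10362340847578,338.816,"synthetic"
1975,-7.11387022701846,339.6875,"synthetic"
1976,-7.12418283592547,340.566,"synthetic"
1977,-7.13456113043322,341.4515,"synthetic"
1978,-7.14500500677119,342.344,"synthetic"
1979,-7.15551436214476,343.2435,"synthetic"
1980,-7.16608909471857,344.15,"synthetic"
1981,-7.17672910360018,345.0635,"synthetic"
1982,-7.18743428882424,345.984,"synthetic"
1983,-7.19820455133695,346.9115,"synthetic"
1984,-7.20903979298096,347.846,"synthetic"
1985,-7.21993991648059,348.7875,"synthetic"
1986,-7.23090482542743,349.736,"synthetic"
1987,-7.24193442426627,350.6915,"synthetic"
1988,-7.25302861828136,351.654,"synthetic"
1989,-7.26418731358295,352.6235,"synthetic"
1990,-7.27541041709426,353.6,"synthetic"
1991,-7.28669783653857,354.5835,"synthetic"
1992,-7.29804948042677,355.574,"synthetic"
1993,-7.30946525804512,356.5715,"synthetic"
1994,-7.32094507944323,357.576,"synthetic"
1995,-7.33248885542244,358.5875,"synthetic"
1996,-7.34409649752431,359.606,"synthetic"
1997,-7.35576791801951,360.6315,"synthetic"
1998,-7.3675030298968,361.664,"synthetic"
1999,-7.3793017468524,362.7035,"synthetic"
2000,-7.39116398327946,363.75,"synthetic"
2001,-7.40308965425784,364.8035,"synthetic"
2002,-7.41507867554405,365.864,"synthetic"
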